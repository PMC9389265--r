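#' 2D grayscale image with a validity mask
#'
#' The basic raster container used throughout the package: a numeric matrix of
#' intensities in `[0, 1]` plus a logical mask of the same shape marking which
#' pixels carry real data. Pixels outside the mask (e.g. regions exposed by a
#' geometric transform) hold the fill value 0 and are excluded from joint
#' histograms.
#'
#' @param pixels numeric matrix of intensities.
#' @param valid_mask logical matrix of the same shape, or `NULL` for all-valid.
#' @param normalize if `TRUE`, min-max rescale `pixels` to `[0, 1]` over the
#'   valid region before validation (constant images map to 0).
#' @return An object of class `image2d`: a list with elements `pixels` and
#'   `mask`.
#' @examples
#' img <- image2d(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
image2d <- function(pixels, valid_mask = NULL, normalize = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be nonempty")
  storage.mode(pixels) <- "double"
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), dim(pixels)))
    stop("`valid_mask` must be a logical matrix with the same shape as `pixels`")
  if (!any(valid_mask))
    stop("image must have at least one valid pixel")
  if (anyNA(pixels) || any(!is.finite(pixels[valid_mask])))
    stop("intensities must be finite")
  if (normalize) {
    v <- pixels[valid_mask]
    rng <- range(v)
    pixels[valid_mask] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
    pixels[!valid_mask] <- 0
  }
  if (any(pixels[valid_mask] < 0) || any(pixels[valid_mask] > 1))
    stop("intensities must lie in [0, 1]; use normalize = TRUE when loading raw data")
  structure(list(pixels = pixels, mask = valid_mask), class = "image2d")
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d, %d/%d valid, intensity [%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask), length(x$mask),
              min(x$pixels[x$mask]), max(x$pixels[x$mask])))
  invisible(x)
}

#' Read a grayscale image from PNG, TIFF or NIfTI
#'
#' PNG and TIFF are read with the standard raster loaders; multi-channel
#' images are averaged to gray. NIfTI volumes require a slice selection when
#' 3D. All images are min-max normalized to `[0, 1]` on load.
#'
#' @param path file path; format chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param slice_axis for 3D NIfTI input, the axis (1, 2 or 3) to slice along.
#' @param slice_index for 3D NIfTI input, the 1-based index of the slice.
#' @return An [image2d].
#' @export
read_image <- function(path, slice_axis = 3L, slice_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    arr <- png::readPNG(path)
    px <- flatten_gray(arr)
  } else if (grepl("\\.tiff?$", lower)) {
    arr <- tiff::readTIFF(path)
    px <- flatten_gray(arr)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    a <- as.array(vol)
    if (length(dim(a)) == 3L) {
      if (is.null(slice_index))
        stop("3D NIfTI input requires `slice_index` (and optionally `slice_axis`)")
      px <- switch(as.integer(slice_axis),
                   a[slice_index, , ], a[, slice_index, ], a[, , slice_index])
      px <- as.matrix(px)
    } else if (length(dim(a)) == 2L) {
      px <- as.matrix(a)
    } else {
      stop("unsupported NIfTI dimensionality: ", length(dim(a)))
    }
  } else {
    stop("unsupported image format: ", path)
  }
  image2d(px, normalize = TRUE)
}

# average channels of a readPNG/readTIFF array down to a gray matrix
flatten_gray <- function(arr) {
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    chans <- min(nc, 3L)   # drop alpha
    px <- arr[, , 1]
    if (chans > 1L) {
      for (k in 2:chans) px <- px + arr[, , k]
      px <- px / chans
    }
    px
  } else {
    arr
  }
}

#' Write an image (or label map) to PNG
#'
#' Intensities are written as 8-bit gray. Label maps are written with the
#' palette `value = label / max(label)` so classes remain distinguishable.
#'
#' @param img an [image2d], or an integer label matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (inherits(img, "image2d")) {
    px <- img$pixels
  } else if (is.matrix(img)) {
    mx <- max(img)
    px <- if (mx > 0) img / mx else img * 0
  } else {
    stop("`img` must be an image2d or a matrix")
  }
  png::writePNG(px, target = path)
  invisible(path)
}
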