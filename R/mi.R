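#' Joint intensity histogram of two aligned images
#'
#' Intensities are quantized into `bins` equal-width levels over `[0, 1]`
#' (the last bin right-closed, so an intensity of exactly 1 lands in the top
#' bin). A pixel contributes one count to cell `(level_ref, level_moved)`
#' only where both validity masks are true; the total is therefore the size
#' of the jointly valid region.
#'
#' @param ref,moved [image2d] objects of identical shape.
#' @param bins number of intensity levels per image (>= 2; default 64).
#' @return An object of class `joint_histogram`: list with `bins`, `counts`
#'   (a `bins x bins` integer matrix, reference level indexing rows) and
#'   `total`.
#' @export
joint_histogram <- function(ref, moved, bins = 64L) {
  stopifnot(inherits(ref, "image2d"), inherits(moved, "image2d"))
  if (!identical(dim(ref$pixels), dim(moved$pixels)))
    stop("`ref` and `moved` must have identical shape")
  bins <- as.integer(bins)
  if (bins < 2L) stop("`bins` must be at least 2")
  counts <- .joint_hist_cpp(ref$pixels, moved$pixels, ref$mask, moved$mask, bins)
  total <- sum(counts)
  if (total == 0L)
    stop("degenerate overlap: no jointly valid pixels")
  structure(list(bins = bins, counts = counts, total = total),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram %d x %d bins, %d counts>\n",
              x$bins, x$bins, x$total))
  invisible(x)
}

#' Mutual information of a joint histogram (bits)
#'
#' Computes `sum p(a,b) log2( p(a,b) / (p(a) p(b)) )` over the joint
#' distribution `p = counts / total`, skipping `0 log 0` terms. The result is
#' non-negative up to rounding; tiny negative values are clamped to 0. Base-2
#' logarithms are used throughout, so scores are in bits; the choice of base
#' only rescales the registration objective and cannot move its argmax.
#'
#' @param hist a [joint_histogram], or a square matrix of non-negative
#'   counts/probabilities.
#' @return Mutual information in bits.
#' @examples
#' mutual_information(matrix(c(0.5, 0, 0, 0.5), 2, 2))  # 1 bit
#' @export
mutual_information <- function(hist) {
  if (inherits(hist, "joint_histogram")) {
    counts <- hist$counts
  } else if (is.matrix(hist) && nrow(hist) == ncol(hist)) {
    if (any(hist < 0)) stop("histogram entries must be non-negative")
    if (sum(hist) <= 0) stop("histogram must have positive total")
    # probabilities are accepted for convenience; rescale-free formula
    return(mi_real(hist))
  } else {
    stop("`hist` must be a joint_histogram or a square matrix")
  }
  .mi_counts_cpp(counts)
}

# direct real-valued MI (used for probability matrices); terms for cells
# (i,j) and (j,i) are paired commutatively so the value is exactly invariant
# under transposition
mi_real <- function(p) {
  p <- p / sum(p)
  pa <- rowSums(p); pb <- colSums(p)
  term <- p * 0
  nz <- p > 0
  term[nz] <- p[nz] * log2(p[nz] / outer(pa, pb)[nz])
  u <- term + t(term)
  mi <- sum(u[upper.tri(u)]) + sum(diag(term))
  max(mi, 0)
}

#' Mutual-information similarity of a candidate transform
#'
#' The registration objective: the floating image is resampled under
#' `params` and its mutual information with the reference is computed on the
#' jointly valid region. A transform that leaves no jointly valid pixels
#' scores 0 (the worst possible value) instead of erroring, so optimizers
#' can move back toward the frame.
#'
#' @param ref the fixed reference [image2d].
#' @param flt the floating [image2d].
#' @param params candidate [transform_params].
#' @param bins histogram bins (default 64).
#' @return Similarity in bits (>= 0).
#' @export
similarity <- function(ref, flt, params, bins = 64L) {
  stopifnot(inherits(ref, "image2d"), inherits(flt, "image2d"))
  if (!identical(dim(ref$pixels), dim(flt$pixels)))
    stop("`ref` and `flt` must have identical shape")
  params <- as_transform_params(params)
  .mi_transform_cpp(ref$pixels, ref$mask, flt$pixels, flt$mask,
                    params[["x"]], params[["y"]], params[["theta"]],
                    params[["Z"]], as.integer(bins))
}

#' Build a fast similarity objective closure
#'
#' Precomputes everything reusable and returns `function(p)` mapping a
#' numeric vector `c(x, y, theta, Z)` to the MI similarity in bits. This is
#' the opaque objective contract shared by every optimizer in the package;
#' the optimizers never touch pixels directly.
#'
#' @inheritParams similarity
#' @return A function from a length-4 numeric vector to a similarity score.
#' @export
make_objective <- function(ref, flt, bins = 64L) {
  stopifnot(inherits(ref, "image2d"), inherits(flt, "image2d"))
  if (!identical(dim(ref$pixels), dim(flt$pixels)))
    stop("`ref` and `flt` must have identical shape")
  bins <- as.integer(bins)
  rp <- ref$pixels; rm <- ref$mask; fp <- flt$pixels; fm <- flt$mask
  function(p) {
    .mi_transform_cpp(rp, rm, fp, fm, p[[1]], p[[2]], p[[3]], p[[4]], bins)
  }
}
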