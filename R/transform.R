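#' Rigid+scale transform parameters
#'
#' The candidate solution optimized during registration: a translation,
#' rotation and isotropic scale. Axis conventions follow the registration
#' protocol this package implements and differ from the usual image-indexing
#' convention, so they are spelled out here:
#'
#' * `x` — displacement along the **vertical** axis in pixels, positive = up
#'   (toward row 0);
#' * `y` — displacement along the **horizontal** axis in pixels, positive =
#'   left (toward column 0);
#' * `theta` — rotation in degrees, positive = counterclockwise on screen;
#'   stored unwrapped, compared modulo 360;
#' * `Z` — unitless isotropic scale factor about the image center, `Z > 0`.
#'
#' The forward composition is fixed as: scale by `Z` about the image center,
#' then rotate by `theta` about the center, then translate. Ground-truth
#' inverses (see [invert_params()]) are defined with respect to this order.
#'
#' @param x,y translation components (pixels).
#' @param theta rotation (degrees, CCW positive).
#' @param Z isotropic scale factor (must be positive).
#' @return An object of class `transform_params` (named numeric vector).
#' @examples
#' p <- transform_params(8, 6, 5, 1)
#' invert_params(p)
#' @export
transform_params <- function(x = 0, y = 0, theta = 0, Z = 1) {
  p <- c(x = as.numeric(x), y = as.numeric(y),
         theta = as.numeric(theta), Z = as.numeric(Z))
  if (anyNA(p) || any(!is.finite(p))) stop("transform parameters must be finite")
  if (p[["Z"]] <= 0) stop("scale factor Z must be positive")
  structure(p, class = "transform_params")
}

as_transform_params <- function(p) {
  if (inherits(p, "transform_params")) return(p)
  transform_params(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf("<transform: x=%+.4f px (up)  y=%+.4f px (left)  theta=%+.4f deg  Z=%.4f>\n",
              x[["x"]], x[["y"]], x[["theta"]], x[["Z"]]))
  invisible(x)
}

#' Exact inverse of a rigid+scale transform
#'
#' Returns the parameters that undo `params` under the package's fixed
#' composition order (scale, rotate, translate). Applying a transform and
#' then its inverse reproduces the input on the jointly valid region up to
#' interpolation loss.
#'
#' @param params a [transform_params].
#' @return A [transform_params].
#' @export
invert_params <- function(params) {
  params <- as_transform_params(params)
  x <- params[["x"]]; y <- params[["y"]]
  th <- params[["theta"]] * pi / 180; Z <- params[["Z"]]
  # forward in (h right, v up): p' = R(theta) Z p + (-y, x)
  # inverse translation: t' = -R(-theta) t / Z with t = (-y, x)
  th_h <- (y * cos(th) - x * sin(th)) / Z
  th_v <- -(y * sin(th) + x * cos(th)) / Z
  transform_params(x = th_v, y = -th_h, theta = -params[["theta"]], Z = 1 / Z)
}

#' Resample an image under a rigid+scale transform
#'
#' Inverse-mapping bilinear resampling: for every output pixel the source
#' coordinate is found by applying the inverse of (scale by `Z` about the
#' center, rotate `theta` CCW about the center, translate `x` up / `y` left),
#' and the input is interpolated bilinearly there. Source coordinates outside
#' the input domain — or touching any masked-out input pixel — produce fill
#' value 0 with `valid_mask = FALSE`.
#'
#' Quarter-turn rotations combined with integer translations and `Z = 1` are
#' resolved exactly (pure index permutation, no interpolation).
#'
#' @param img an [image2d].
#' @param params a [transform_params] (or numeric vector `c(x, y, theta, Z)`).
#' @return An [image2d] of the same shape as `img`.
#' @export
apply_transform <- function(img, params) {
  stopifnot(inherits(img, "image2d"))
  params <- as_transform_params(params)
  out <- .resample_cpp(img$pixels, img$mask,
                       params[["x"]], params[["y"]],
                       params[["theta"]], params[["Z"]])
  structure(list(pixels = out$pixels, mask = out$mask), class = "image2d")
}
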