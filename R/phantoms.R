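#' Specification for a synthetic brain-slice phantom
#'
#' The phantom generator stands in for a real brain atlas slice: a nested-
#' ellipse "head" with four tissue classes — background, a CSF-like class
#' (outer rim plus two ventricle-like ellipses), gray matter and white
#' matter — plus seeded Gaussian intensity noise. It is a pure function of
#' the spec, so fixtures are reproducible everywhere.
#'
#' @param size square side length in pixels (>= 32; default 128).
#' @param noise_sd standard deviation of the per-pixel Gaussian intensity
#'   noise, in intensity units (must be < 0.5; default 0.02).
#' @param seed integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 128L, noise_sd = 0.02, seed = 1L) {
  size <- as.integer(size)
  if (size < 32L) stop("phantom size must be at least 32 pixels")
  if (noise_sd < 0 || noise_sd >= 0.5) stop("`noise_sd` must be in [0, 0.5)")
  structure(list(size = size,
                 tissue_classes = c("background", "csf", "gray", "white"),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# label codes used throughout: 0 background, 1 csf, 2 gray, 3 white
PHANTOM_LABELS <- c(background = 0L, csf = 1L, gray = 2L, white = 3L)

# base intensities of the single-contrast (density-like) phantom
PHANTOM_INTENSITY <- c(background = 0.05, csf = 0.30, gray = 0.55, white = 0.85)

# per-class intensity lookups for the modality pair: the CSF class is dark
# on the T1-like contrast and bright on the T2-like contrast
T1_INTENSITY <- c(background = 0.05, csf = 0.12, gray = 0.55, white = 0.82)
T2_INTENSITY <- c(background = 0.05, csf = 0.90, gray = 0.45, white = 0.20)

phantom_label_map <- function(n) {
  ys <- seq(-1, 1, length.out = n)          # rows, top to bottom
  xs <- seq(-1, 1, length.out = n)          # columns, left to right
  R <- matrix(ys, n, n)
  C <- matrix(xs, n, n, byrow = TRUE)
  lab <- matrix(PHANTOM_LABELS[["background"]], n, n)
  inside <- function(rc, cc, ar, ac) ((R - rc) / ar)^2 + ((C - cc) / ac)^2 <= 1
  lab[inside(0, 0, 0.88, 0.72)] <- PHANTOM_LABELS[["csf"]]    # head; rim stays CSF
  lab[inside(0, 0, 0.80, 0.64)] <- PHANTOM_LABELS[["gray"]]
  lab[inside(0, 0, 0.58, 0.44)] <- PHANTOM_LABELS[["white"]]
  lab[inside(-0.08, -0.16, 0.30, 0.10)] <- PHANTOM_LABELS[["csf"]]  # ventricles
  lab[inside(-0.08, 0.16, 0.30, 0.10)] <- PHANTOM_LABELS[["csf"]]
  lab
}

labels_to_image <- function(lab, lookup, noise_sd, seed) {
  px <- matrix(lookup[lab + 1L], nrow(lab), ncol(lab))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    px <- px + matrix(rnorm(length(px), 0, noise_sd), nrow(px), ncol(px))
    px <- pmin(pmax(px, 0), 1)
  }
  image2d(px)
}

#' Generate a brain-like phantom slice
#'
#' @param spec a [phantom_spec].
#' @return A list with `image` (an [image2d]) and `labels` (an integer
#'   matrix; 0 background, 1 CSF, 2 gray matter, 3 white matter).
#' @examples
#' ph <- make_phantom(phantom_spec(size = 64))
#' table(ph$labels)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_label_map(spec$size)
  img <- labels_to_image(lab, unname(PHANTOM_INTENSITY), spec$noise_sd, spec$seed)
  list(image = img, labels = lab)
}

#' Generate a T1/T2-like multimodal pair from one label map
#'
#' Both images come from the same anatomy (label map) through different
#' per-class intensity lookups with independent noise, emulating
#' multimodal MRI contrast: the CSF-like class has low signal on the
#' T1-like image (lowest third of the intensity range) and high signal on
#' the T2-like image (highest third), and white/gray contrast also inverts.
#' Noise seeds are derived from `spec$seed` (offsets +1 and +2) so the pair
#' is reproducible and independent of the phantom's own noise draw.
#'
#' @param phantom the phantom [image2d] the labels came from (shape check
#'   only; intensities are re-derived from the labels).
#' @param labels integer label matrix from [make_phantom()].
#' @param spec the [phantom_spec].
#' @return A list with `t1` and `t2` ([image2d] objects).
#' @export
make_modality_pair <- function(phantom, labels, spec) {
  stopifnot(inherits(spec, "phantom_spec"), is.matrix(labels))
  if (inherits(phantom, "image2d") &&
      !identical(dim(phantom$pixels), dim(labels)))
    stop("`labels` must be aligned with `phantom`")
  t1 <- labels_to_image(labels, unname(T1_INTENSITY), spec$noise_sd, spec$seed + 1L)
  t2 <- labels_to_image(labels, unname(T2_INTENSITY), spec$noise_sd, spec$seed + 2L)
  list(t1 = t1, t2 = t2)
}

#' Build a floating image with known ground truth
#'
#' Applies `true_params` to `img` to create the floating image of a
#' registration experiment. The registration ground truth — the transform a
#' perfect optimizer should recover — is the exact inverse of `true_params`
#' under the package's composition order; it is attached as the
#' `"true_inverse"` attribute (and `true_params` as `"true_params"`).
#'
#' @param img the reference [image2d].
#' @param true_params the construction transform ([transform_params]).
#' @return An [image2d] with attributes `true_params` and `true_inverse`.
#' @examples
#' ph <- make_phantom(phantom_spec(size = 64, noise_sd = 0))
#' flt <- make_float(ph$image, transform_params(8, 6, 5, 1))
#' attr(flt, "true_inverse")
#' @export
make_float <- function(img, true_params) {
  true_params <- as_transform_params(true_params)
  out <- apply_transform(img, true_params)
  attr(out, "true_params") <- true_params
  attr(out, "true_inverse") <- invert_params(true_params)
  out
}
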