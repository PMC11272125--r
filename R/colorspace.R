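#' Convert an RGB image to CIELAB
#'
#' Vectorised sRGB (8-bit, D65) to CIELAB conversion via the standard
#' sRGB -> linear RGB -> XYZ -> LAB chain. `L` is in `[0, 100]`; `a` and `b`
#' are the usual opponent axes.
#'
#' @param img An RGB image: `height x width x 3` numeric array with values in
#'   `[0, 255]` (8-bit) or `[0, 1]`.
#' @return A `height x width x 3` array with channels `L`, `a`, `b`.
#' @examples
#' px <- array(c(255, 255, 255), dim = c(1, 1, 3))
#' rgb_to_lab(px)[1, 1, ]  # L = 100, a ~ 0, b ~ 0
#' @export
rgb_to_lab <- function(img) {
  img <- validate_rgb(img)
  d <- dim(img)
  rgb <- matrix(img, ncol = 3L)
  # inverse sRGB companding
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3L, byrow = TRUE)
  xyz <- lin %*% t(m)
  # D65 reference white
  white <- c(0.95047, 1.00000, 1.08883)
  xyz <- sweep(xyz, 2L, white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(L = 116 * f[, 2L] - 16,
               a = 500 * (f[, 1L] - f[, 2L]),
               b = 200 * (f[, 2L] - f[, 3L]))
  array(lab, dim = d, dimnames = list(NULL, NULL, c("L", "a", "b")))
}

#' Convert an RGB tile to the nucleus-signal grayscale
#'
#' Produces the single-channel image used for thresholding and segmentation:
#' the image is transformed to CIELAB, each channel is standardised by its
#' mean and standard deviation, and the standardised complement of lightness
#' (haematoxylin-dark nuclei scoring high) is affinely rescaled to `[0, 1]`.
#'
#' @inheritParams rgb_to_lab
#' @return A `height x width` matrix in `[0, 1]`; high values mark nuclear
#'   (haematoxylin-positive) signal.
#' @seealso [otsu_threshold()], [segment_slide()]
#' @export
to_nucleus_grayscale <- function(img) {
  lab <- rgb_to_lab(img)
  L <- lab[, , 1L]
  s <- sd(L)
  if (!is.finite(s) || s == 0) {
    s_all <- c(sd(lab[, , 1L]), sd(lab[, , 2L]), sd(lab[, , 3L]))
    if (all(s_all == 0))
      stopf("degenerate image: all channels are constant")
    stopf("degenerate image: lightness channel is constant")
  }
  z <- -(L - mean(L)) / s         # complement of lightness, standardised
  rng <- range(z)
  (z - rng[1L]) / (rng[2L] - rng[1L])
}

#' Absolute nucleus-intensity channel
#'
#' The complement of CIELAB lightness, `(100 - L) / 100`, on a fixed scale:
#' unlike [to_nucleus_grayscale()] (which standardises per slide and is used
#' for thresholding), this channel is comparable across slides and is the
#' reference used for intensity and texture features.
#'
#' @inheritParams rgb_to_lab
#' @return A `height x width` matrix in `[0, 1]`.
#' @export
nucleus_intensity <- function(img) {
  L <- rgb_to_lab(img)[, , 1L]
  pmin(pmax((100 - L) / 100, 0), 1)
}

# Accept arrays in [0,255] or [0,1]; return [0,1] array h x w x 3.
validate_rgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3L] == 3L))
    stopf("expected an RGB array of dimension height x width x 3")
  if (any(!is.finite(img))) stopf("RGB image contains non-finite values")
  if (max(img) > 1) img <- img / 255
  if (min(img) < 0 || max(img) > 1)
    stopf("RGB values must lie in [0, 255] (or [0, 1])")
  img
}
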