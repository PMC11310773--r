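# Color feature extraction: each pixel is described by 9 values spanning
# RGB, HSV and CIELAB, the feature set commonly used for color-based
# vegetation/soil separation.

#' RGB to HSV
#'
#' Standard hexcone HSV with hue scaled to `[0, 1)` (red at 0) and hue
#' conventionally 0 for achromatic pixels.
#'
#' @param r,g,b intensities in 0-255 (vectors of equal length).
#' @return a matrix with columns `h`, `s`, `v` in `[0, 1]`.
#' @export
rgb_to_hsv <- function(r, g, b) {
  out <- t(grDevices::rgb2hsv(r = r, g = g, b = b, maxColorValue = 255))
  colnames(out) <- c("h", "s", "v")
  out[out[, "h"] >= 1, "h"] <- 0
  out
}

# sRGB (D65, 2 deg observer) -> CIEXYZ matrix, IEC 61966-2-1
SRGB_TO_XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                        0.2126729, 0.7151522, 0.0721750,
                        0.0193339, 0.1191920, 0.9503041),
                      nrow = 3L, byrow = TRUE)

#' RGB to CIELAB
#'
#' Treats input as sRGB and converts through linear RGB and XYZ to CIELAB
#' under the D65 white point (2 degree observer).
#'
#' @param r,g,b intensities in 0-255 (vectors of equal length).
#' @return a matrix with columns `L` (0-100), `a_star`, `b_star`.
#' @export
rgb_to_lab <- function(r, g, b) {
  srgb <- cbind(r, g, b) / 255
  lin <- ifelse(srgb <= 0.04045, srgb / 12.92,
                ((srgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(SRGB_TO_XYZ)
  white <- rowSums(SRGB_TO_XYZ)   # XYZ of sRGB white = row sums of the matrix
  tt <- sweep(xyz, 2L, white, `/`)
  delta <- 6 / 29
  f <- ifelse(tt > delta^3, tt^(1 / 3), tt / (3 * delta^2) + 4 / 29)
  cbind(L = 116 * f[, 2L] - 16,
        a_star = 500 * (f[, 1L] - f[, 2L]),
        b_star = 200 * (f[, 2L] - f[, 3L]))
}

#' 9-dimensional color feature vector
#'
#' Stacks normalized RGB, HSV and CIELAB for each input pixel.
#'
#' @param r,g,b intensities in 0-255.
#' @return a numeric matrix with columns
#'   `r, g, b, h, s, v, L, a_star, b_star`.
#' @export
color_features <- function(r, g, b) {
  cbind(r = r / 255, g = g / 255, b = b / 255,
        rgb_to_hsv(r, g, b), rgb_to_lab(r, g, b))
}
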