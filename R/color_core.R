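#' @useDynLib electrodecam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- sRGB linearization ----------------------------------------------------

srgb_decompress <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

srgb_compress <- function(v) {
  ifelse(v <= 0.04045 / 12.92, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055)
}

# 256-entry lookup table mapping 8-bit gamma-compressed channel values to
# linear [0,1]; computed once per session.
srgb_lut8 <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) lut <<- srgb_decompress((0:255) / 255)
    lut
  }
})

#' Linearize a gamma-compressed color image
#'
#' Converts an 8-bit sRGB (gamma-compressed) image into a linear RGB image
#' with channels in \[0, 1\]. Integer inputs go through a 256-entry lookup
#' table; numeric inputs in \[0, 1\] are decompressed with the continuous
#' sRGB curve (used for synthetic imagery rendered at full precision).
#'
#' @param raw integer array (H x W x 3, values 0..255) or numeric array in
#'   \[0, 1\] of gamma-compressed values.
#' @return numeric array H x W x 3 of linear values in \[0, 1\], class
#'   `linear_rgb`.
#' @export
linearize <- function(raw) {
  if (is.integer(raw) || (is.numeric(raw) && max(raw, na.rm = TRUE) > 1 + 1e-9)) {
    stopifnot(min(raw) >= 0, max(raw) <= 255)
    out <- array(srgb_lut8()[as.integer(round(raw)) + 1L], dim = dim(raw))
  } else {
    stopifnot(min(raw) >= 0, max(raw) <= 1 + 1e-12)
    out <- array(srgb_decompress(pmin(raw, 1)), dim = dim(raw))
  }
  structure(out, class = "linear_rgb")
}

#' Gamma-compress a linear image back to 8-bit sRGB
#'
#' @param img numeric array of linear values in \[0, 1\].
#' @param bits target bit depth (8 gives integers 0..255).
#' @return integer array of gamma-compressed values.
#' @export
gamma_compress8 <- function(img, bits = 8L) {
  mx <- 2^bits - 1
  out <- as.integer(round(srgb_compress(pmin(pmax(img, 0), 1)) * mx))
  if (!is.null(dim(img))) dim(out) <- dim(img)
  out
}

# ---- chromaticity ----------------------------------------------------------

#' Decompose a linear image into chromaticity and intensity
#'
#' Per pixel, intensity I = R + G + B (so 0 <= I <= 3) and chromaticities
#' r = R/I, g = G/I, b = B/I. Zero-intensity pixels are flagged undefined
#' rather than carrying NaNs.
#'
#' @param img linear RGB array (H x W x 3) in \[0, 1\].
#' @return object of class `chromaticity`: list with matrices `r`, `g`, `b`,
#'   `I` and logical matrix `defined`.
#' @export
to_chromaticity <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  R <- matrix(img[, , 1], h, w)
  G <- matrix(img[, , 2], h, w)
  B <- matrix(img[, , 3], h, w)
  I <- R + G + B
  defined <- I > 0
  Iw <- ifelse(defined, I, 1)   # avoid 0/0; undefined pixels masked anyway
  structure(list(r = R / Iw, g = G / Iw, b = B / Iw, I = I, defined = defined),
            class = "chromaticity")
}

#' Reassemble a linear RGB image from chromaticity and intensity
#'
#' @param chrom `chromaticity` object.
#' @return linear RGB array; undefined pixels become black.
#' @export
from_chromaticity <- function(chrom) {
  I <- ifelse(chrom$defined, chrom$I, 0)
  arr <- array(0, dim = c(dim(I), 3L))
  arr[, , 1] <- chrom$r * I
  arr[, , 2] <- chrom$g * I
  arr[, , 3] <- chrom$b * I
  structure(arr, class = "linear_rgb")
}

#' Gray-gamut target
#'
#' The neutral (5500 K) color gamut point, its chromaticity spreads, and the
#' linear-domain exposure band used to pick usable gray pixels.
#'
#' @param cfg pipeline configuration.
#' @return object of class `gamut_target`.
#' @export
gamut_target <- function(cfg = el_config()) {
  g <- cfg$color$gamut
  stopifnot(abs(g$r + g$g + g$b - 1) < 1e-3,
            g$sigma_r > 0, g$sigma_g > 0, g$sigma_b > 0,
            g$i_min >= 0, g$i_min < g$i_max, g$i_max <= 1)
  structure(list(r = g$r, g = g$g, b = g$b,
                 sigma_r = g$sigma_r, sigma_g = g$sigma_g, sigma_b = g$sigma_b,
                 i_min = g$i_min, i_max = g$i_max,
                 max_intensity = cfg$color$max_intensity,
                 sigma_squared = cfg$color$ellipse_sigma_squared),
            class = "gamut_target")
}

#' Select gray (near-neutral) pixels
#'
#' A pixel qualifies as gray when its chromaticity falls inside both
#' axis-aligned ellipses around the neutral gamut point (red-green and
#' blue-green) and its intensity lies inside the exposure band
#' `(i_min, i_max)` scaled by the maximum intensity.
#'
#' @param chrom `chromaticity` object.
#' @param target `gamut_target`.
#' @return logical matrix; an all-`FALSE` result is valid (caller decides the
#'   fallback).
#' @export
select_gray_pixels <- function(chrom, target = gamut_target()) {
  p <- if (isTRUE(target$sigma_squared)) 2 else 1
  e1 <- (chrom$r - target$r)^2 / target$sigma_r^p +
        (chrom$g - target$g)^2 / target$sigma_g^p
  e2 <- (chrom$b - target$b)^2 / target$sigma_b^p +
        (chrom$g - target$g)^2 / target$sigma_g^p
  band_lo <- target$i_min * target$max_intensity
  band_hi <- target$i_max * target$max_intensity
  chrom$defined & e1 <= 1 & e2 <= 1 & chrom$I > band_lo & chrom$I < band_hi
}
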