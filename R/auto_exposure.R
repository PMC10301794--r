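# Patient-masked histogram-skewness exposure controller. Online it drives
# exposure time and gain toward a symmetric gray-value histogram of the
# torso pixels; offline the skewness serves as a per-frame exposure score.

# linearized bin boundaries: 256 gamma-domain bins over gray value V in
# [0,1], boundaries mapped into the linear intensity domain [0, maxI]
linear_bin_boundaries <- function(n_bins = 256, max_intensity = 3) {
  srgb_decompress(seq_len(n_bins - 1) / n_bins) * max_intensity
}

#' Masked exposure histogram
#'
#' Histogram of gamma-domain gray values over the masked, properly exposed
#' pixels of an intensity image. Bins are assigned by a left-bisection
#' search over precomputed linearized bin boundaries, avoiding a per-pixel
#' gamma compression.
#'
#' @param chrom `chromaticity` object (its `I` plane is used).
#' @param mask logical matrix aligned with the intensity plane (the depth
#'   segmentation mask mapped into the color image).
#' @param target `gamut_target` providing the exposure band.
#' @param n_bins number of gray-value bins.
#' @return integer vector of bin counts (names 0..n_bins-1) with attribute
#'   `empty` when no pixel qualified.
#' @export
masked_histogram <- function(chrom, mask, target = gamut_target(),
                             n_bins = 256) {
  stopifnot(all(dim(mask) == dim(chrom$I)))
  band <- c(target$i_min, target$i_max) * target$max_intensity
  use <- mask & chrom$defined & chrom$I > band[1] & chrom$I < band[2]
  bounds <- linear_bin_boundaries(n_bins, target$max_intensity)
  bins <- findInterval(chrom$I[use], bounds)   # 0..n_bins-1
  h <- tabulate(bins + 1L, nbins = n_bins)
  names(h) <- as.character(seq_len(n_bins) - 1L)
  if (!any(use)) attr(h, "empty") <- TRUE
  h
}

#' Histogram skewness about mid-gray
#'
#' Standardized third central moment of the gray-value histogram about bin
#' value 128, using precomputed per-bin `(v-128)^2` and `(v-128)^3` tables:
#' `S = m3 / m2^(3/2)`. Zero when the second moment vanishes.
#'
#' @param h histogram as returned by [masked_histogram()].
#' @return skewness score; negative for underexposed (dark-heavy) frames.
#' @export
histogram_skewness <- function(h) {
  n <- sum(h)
  if (n == 0) return(0)
  v <- seq_along(h) - 1L
  d2 <- (v - 128)^2
  d3 <- (v - 128)^3
  m2 <- sum(h * d2) / n
  m3 <- sum(h * d3) / n
  if (m2 <= 0) return(0)
  m3 / m2^1.5
}

#' Exposure controller state
#'
#' @param tau_star overall (virtual) exposure parameter, ms.
#' @param cfg pipeline configuration (`exposure` section).
#' @return object of class `exposure_state`.
#' @export
exposure_state <- function(tau_star = 30, cfg = el_config()) {
  e <- cfg$exposure
  tau_ref <- min(max(e$tau_frame, e$tau_range[1]), e$tau_range[2])
  structure(list(tau_star = tau_star, tau_ref = tau_ref,
                 n_tau = e$n_tau, tau_delta = e$tau_delta,
                 tau_range = e$tau_range, gain_range = e$gain_range),
            class = "exposure_state")
}

#' One exposure-control update
#'
#' Applies the skewness-driven update
#' `tau*_{n+1} = tau*_n - S * tau_delta * N_tau * gain_n`, then splits the
#' overall exposure into the clamped gain `tau*/tau**` and the clamped
#' exposure time `tau*/gain`.
#'
#' @param state `exposure_state`.
#' @param cam `camera_state`.
#' @param S histogram skewness of the current frame.
#' @return list with updated `state` and `cam`.
#' @export
update_exposure <- function(state, cam, S) {
  state$tau_star <- state$tau_star - S * state$tau_delta * state$n_tau * cam$gain
  state$tau_star <- max(state$tau_star, state$tau_range[1])
  gain <- min(max(state$tau_star / state$tau_ref, state$gain_range[1]),
              state$gain_range[2])
  tau <- min(max(state$tau_star / gain, state$tau_range[1]), state$tau_range[2])
  cam$gain <- gain
  cam$tau <- tau
  list(state = state, cam = cam)
}

#' Score the exposure of recorded frames
#'
#' Offline helper: computes the masked histogram skewness for each view and
#' returns the exposure trace the online controller would log.
#'
#' @param views list of views; each needs a `chromaticity` image `chrom` and
#'   logical `mask` on the color grid.
#' @param target `gamut_target`.
#' @return tibble with `view`, `skewness`, `n_pixels`.
#' @export
score_exposure <- function(views, target = gamut_target()) {
  rows <- lapply(seq_along(views), function(i) {
    v <- views[[i]]
    h <- masked_histogram(v$chrom, v$mask, target)
    tibble::tibble(view = i, skewness = histogram_skewness(h),
                   n_pixels = sum(h))
  })
  do.call(rbind, rows)
}
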