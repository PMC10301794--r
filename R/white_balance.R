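# Automatic white balancing: color-temperature gain model, gray-gamut
# estimation, the online controller step, and the offline virtual-camera
# color correction applied to stored textures.

#' Camera color/exposure state
#'
#' @param KW current white-balance color temperature (K).
#' @param k_range sensor color-temperature range (K).
#' @param tau exposure time (ms), `tau_range` its bounds.
#' @param gain global analog gain, `gain_range` its bounds.
#' @param tau_delta hardware exposure step (ms).
#' @return object of class `camera_state`.
#' @export
camera_state <- function(KW = mean(k_range), k_range = c(2500, 6500),
                         tau = 30, tau_range = c(0.1, 200),
                         gain = 1, gain_range = c(1, 16), tau_delta = 1) {
  stopifnot(KW >= k_range[1], KW <= k_range[2],
            tau >= tau_range[1], tau <= tau_range[2],
            gain >= gain_range[1], gain <= gain_range[2])
  structure(list(KW = KW, k_range = k_range,
                 tau = tau, tau_range = tau_range, tau_delta = tau_delta,
                 gain = gain, gain_range = gain_range),
            class = "camera_state")
}

#' Red/blue channel gains at a color-temperature setting
#'
#' Models how the sensor maps its color-temperature parameter to channel
#' gains: the common gain is
#' `Gamma_K = sqrt(2 (KW - K_min) / (K_max - K_min))`, applied to the red
#' channel directly and to the blue channel as its reciprocal, so that both
#' gains equal 1 at the center of the sensor range.
#'
#' @param KW color temperature (K), strictly above the range minimum.
#' @param k_range sensor range `c(K_min, K_max)`.
#' @return list with `gamma_R`, `gamma_B`, `gamma_K`.
#' @export
gain_model <- function(KW, k_range = c(2500, 6500)) {
  if (KW <= k_range[1] || KW > k_range[2])
    stop("KW must lie in (", k_range[1], ", ", k_range[2], "]")
  gK <- sqrt(2 * (KW - k_range[1]) / (k_range[2] - k_range[1]))
  list(gamma_R = gK, gamma_B = 1 / gK, gamma_K = gK)
}

# inverse of gain_model: color temperature whose gain equals gK (clamped)
gain_to_kelvin <- function(gK, k_range) {
  K <- k_range[1] + gK^2 / 2 * (k_range[2] - k_range[1])
  min(max(K, k_range[1] + 1e-9), k_range[2])
}

#' Gain scaler from mean gray chromaticities
#'
#' The overall color-gain update that moves the mean chromaticity of the
#' selected gray pixels onto the neutral gamut point follows from the
#' red/cyan and yellow/blue chromaticity ratios and reduces to
#' `gamma = sqrt((r_target * b_est) / (r_est * b_target))`; the unknown
#' absolute intensity cancels.
#'
#' @param est list/vector with mean gray chromaticities `r`, `g`, `b`.
#' @param target `gamut_target`.
#' @return `gamma`, or `NA` when the estimate is degenerate (keep current
#'   setting).
#' @export
estimate_scaler <- function(est, target = gamut_target()) {
  if (!is.finite(est$r) || !is.finite(est$b) || est$r <= 0 || est$b <= 0)
    return(NA_real_)
  sqrt((target$r * est$b) / (est$r * target$b))
}

#' Gamut errors before and after a candidate gain update
#'
#' `E` is the squared chromaticity distance between the mean gray estimate
#' and the neutral gamut point. `E*` is the same distance predicted after
#' applying the candidate scaler: with `estar_mode = "renormalized"` the
#' scaler multiplies red by `gamma` and blue by `1/gamma` followed by
#' chromaticity renormalization (the post-update error actually achievable);
#' `"printed"` scales both red and blue by `gamma` without renormalizing.
#'
#' @param est mean gray chromaticities (`r`, `g`, `b`).
#' @param gamma candidate scaler.
#' @param target `gamut_target`.
#' @param estar_mode `"renormalized"` or `"printed"`.
#' @return list with `E` and `Estar`.
#' @export
gamut_errors <- function(est, gamma, target = gamut_target(),
                         estar_mode = "renormalized") {
  E <- (target$r - est$r)^2 + (target$g - est$g)^2 + (target$b - est$b)^2
  if (is.na(gamma)) return(list(E = E, Estar = E))
  if (estar_mode == "printed") {
    Estar <- (target$r - est$r * gamma)^2 + (target$g - est$g)^2 +
             (target$b - est$b * gamma)^2
  } else {
    rr <- est$r * gamma; gg <- est$g; bb <- est$b / gamma
    s <- rr + gg + bb
    Estar <- (target$r - rr / s)^2 + (target$g - gg / s)^2 +
             (target$b - bb / s)^2
  }
  list(E = E, Estar = Estar)
}

# mean chromaticity of selected gray pixels; NULL if none selected
gray_estimate <- function(chrom, target) {
  sel <- select_gray_pixels(chrom, target)
  if (!any(sel)) return(NULL)
  list(r = mean(chrom$r[sel]), g = mean(chrom$g[sel]), b = mean(chrom$b[sel]),
       n = sum(sel))
}

#' One automatic white-balancing step
#'
#' Selects gray pixels, estimates the gain scaler and the gamut errors, and
#' updates the camera's color-temperature setting when the numerically
#' stable acceptance test holds:
#' `E > e_threshold` and `E - E* > e_improve_threshold`. The temperature
#' update converts the scaler into a gain through the sensor gain model and
#' clamps the result to the sensor range.
#'
#' @param chrom `chromaticity` image of the current frame.
#' @param state `camera_state`.
#' @param target `gamut_target`.
#' @param cfg pipeline configuration (`awb` section).
#' @return updated `camera_state` with attribute `awb` carrying diagnostics
#'   (`gamma`, `E`, `Estar`, `n_gray`, `updated`).
#' @export
awb_step <- function(chrom, state, target = gamut_target(), cfg = el_config()) {
  a <- cfg$awb
  est <- gray_estimate(chrom, target)
  diag <- list(gamma = NA_real_, E = NA_real_, Estar = NA_real_,
               n_gray = 0L, updated = FALSE)
  if (is.null(est)) {
    warning("no gray pixels selected; keeping current color temperature")
    attr(state, "awb") <- diag
    return(state)
  }
  gamma <- estimate_scaler(est, target)
  err <- gamut_errors(est, gamma, target, a$estar_mode)
  diag <- list(gamma = gamma, E = err$E, Estar = err$Estar,
               n_gray = est$n, updated = FALSE)
  if (!is.na(gamma) && err$E > a$e_threshold &&
      (err$E - err$Estar) > a$e_improve_threshold) {
    gK <- gain_model(state$KW, state$k_range)$gamma_K
    state$KW <- gain_to_kelvin(gK * gamma, state$k_range)
    diag$updated <- TRUE
  }
  attr(state, "awb") <- diag
  state
}

# render the equal-gain internal representation at setting KW (virtual range)
render_virtual <- function(eq, KW, k_range) {
  gK <- gain_model(KW, k_range)$gamma_K
  out <- eq
  out[, , 1] <- eq[, , 1] * gK
  out[, , 3] <- eq[, , 3] / gK
  out
}

#' Offline virtual-camera color correction of a texture
#'
#' Rebuilds the gain-free internal representation of a recorded texture
#' (red divided by, blue multiplied by, the gain at the recorded color
#' temperature) and re-runs the white-balancing loop on a virtual camera
#' with an extended color-temperature range until the update test fails,
#' consecutive updates change the temperature by at most `jitter_step`, or
#' the jitter fallback fires (mean of the 3 smallest updates among the last
#' `jitter_window` iterations whose consecutive difference stays below
#' `jitter_consec_max`).
#'
#' Pixels overexposed in the input are passed through untouched. Pixels that
#' overflow a channel after rescaling are treated as fully saturated (all
#' channels 1); pixels with any channel below 1e-8 are zeroed; all channels
#' are clipped to 1.
#'
#' @param texture linear RGB array in \[0, 1\] (H x W x 3), or an 8-bit
#'   gamma-compressed array which is linearized first.
#' @param k_recorded color temperature (K) the texture was recorded at; must
#'   lie inside the virtual range.
#' @param target `gamut_target`.
#' @param cfg pipeline configuration.
#' @return list with `texture` (corrected linear RGB), `KW` (converged
#'   temperature), `iterations`, `trace` (per-iteration `KW`, `E`).
#' @export
color_correct_offline <- function(texture, k_recorded,
                                  target = gamut_target(), cfg = el_config()) {
  a <- cfg$awb
  vr <- a$virtual_k_range
  if (k_recorded <= vr[1] || k_recorded > vr[2])
    stop("recorded color temperature outside the virtual camera range")
  if (is.integer(texture) || max(texture) > 1 + 1e-9) texture <- linearize(texture)
  lin <- unclass(texture)

  g_eq <- gain_model(k_recorded, vr)$gamma_K
  eq <- lin
  eq[, , 1] <- lin[, , 1] / g_eq
  eq[, , 3] <- lin[, , 3] * g_eq

  band_hi <- target$i_max * target$max_intensity
  over_in <- to_chromaticity(lin)$I >= band_hi

  KW <- k_recorded
  trace_K <- numeric(0); trace_E <- numeric(0)
  deltas <- numeric(0); K_hist <- numeric(0)
  for (it in seq_len(a$max_iter)) {
    cur <- render_virtual(eq, KW, vr)
    chrom <- to_chromaticity(pmin(pmax(cur, 0), 1))
    est <- gray_estimate(chrom, target)
    if (is.null(est)) break
    gamma <- estimate_scaler(est, target)
    err <- gamut_errors(est, gamma, target, a$estar_mode)
    trace_K <- c(trace_K, KW); trace_E <- c(trace_E, err$E)
    if (is.na(gamma) || err$E <= a$e_threshold ||
        (err$E - err$Estar) <= a$e_improve_threshold) break
    gK <- gain_model(KW, vr)$gamma_K
    KW_new <- gain_to_kelvin(gK * gamma, vr)
    d <- KW_new - KW
    K_hist <- c(K_hist, KW_new); deltas <- c(deltas, d)
    KW <- KW_new
    if (abs(d) <= a$jitter_step) break
    if (length(deltas) >= a$jitter_window) {
      recent_d <- utils::tail(abs(deltas), a$jitter_window)
      recent_K <- utils::tail(K_hist, a$jitter_window)
      consec <- abs(diff(recent_K))
      if (all(consec < a$jitter_consec_max)) {
        ord <- order(recent_d)[1:3]
        KW <- mean(recent_K[ord])
        break
      }
    }
  }

  out <- render_virtual(eq, KW, vr)
  overflow <- out[, , 1] > 1 | out[, , 2] > 1 | out[, , 3] > 1
  under <- out[, , 1] < 1e-8 | out[, , 2] < 1e-8 | out[, , 3] < 1e-8
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[overflow] <- 1
    pl[under] <- 0
    out[, , ch] <- pmin(pl, 1)
  }
  # overexposed input pixels pass through unmodified
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[over_in] <- lin[, , ch][over_in]
    out[, , ch] <- pl
  }
  list(texture = structure(out, class = "linear_rgb"), KW = KW,
       iterations = length(trace_K),
       trace = tibble::tibble(iteration = seq_along(trace_K),
                              KW = trace_K, E = trace_E))
}
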