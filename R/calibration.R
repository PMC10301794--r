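# Marker-color calibration: a 2D chromaticity heat map over manually
# masked clip pixels, median filtering, peak detection, and extraction of
# the red/blue Gaussian components whose covariances define the
# classification ellipses.

#' Build the chromaticity heat map
#'
#' 2D histogram over (r, g) chromaticity with `n_bins` bins per axis,
#' restricted to masked, properly exposed pixels, then median-filtered
#' with the configured neighbourhood.
#'
#' @param chroms list of `chromaticity` images (or a single one).
#' @param masks list of logical matrices selecting clip pixels.
#' @param target `gamut_target` providing the exposure band.
#' @param cfg pipeline configuration (`calibration` section).
#' @return `n_bins` x `n_bins` count matrix (rows: r bins, cols: g bins).
#' @export
build_heatmap <- function(chroms, masks, target = gamut_target(),
                          cfg = el_config()) {
  cb <- cfg$calibration
  if (inherits(chroms, "chromaticity")) chroms <- list(chroms)
  if (is.matrix(masks)) masks <- list(masks)
  nb <- cb$n_bins
  H <- matrix(0L, nb, nb)
  band <- c(target$i_min, target$i_max) * target$max_intensity
  any_px <- FALSE
  for (i in seq_along(chroms)) {
    ch <- chroms[[i]]; mk <- masks[[i]]
    use <- mk & ch$defined & ch$I > band[1] & ch$I < band[2]
    if (!any(use)) next
    any_px <- TRUE
    ri <- pmin(pmax(floor(ch$r[use] * nb), 0), nb - 1) + 1L
    gi <- pmin(pmax(floor(ch$g[use] * nb), 0), nb - 1) + 1L
    H <- H + matrix(tabulate((gi - 1L) * nb + ri, nbins = nb * nb), nb, nb)
  }
  if (!any_px) stop("no usable masked pixels for the heat map")
  median_filter2(H, cb$median_size)
}

# square median filter on a count matrix (zero-padded border)
median_filter2 <- function(m, size = 7) {
  half <- size %/% 2
  nr <- nrow(m); nc <- ncol(m)
  stack <- array(0, c(nr, nc, size * size))
  k <- 0
  for (dr in -half:half) for (dc in -half:half) {
    k <- k + 1
    stack[, , k] <- shift_mat(m, dr, dc)
  }
  apply(stack, c(1, 2), stats::median)
}

#' Find peaks on the heat map
#'
#' Binarizes at `mean + factor * sd` of the nonzero bins and keeps
#' 4-connected regions of at least the configured number of bins.
#'
#' @param NH heat map matrix.
#' @param cfg pipeline configuration.
#' @return list of peak regions; each has `bins` (index matrix) and
#'   `centroid` (r, g in \[0, 1\]).
#' @export
find_peaks <- function(NH, cfg = el_config()) {
  cb <- cfg$calibration
  nz <- NH[NH > 0]
  if (length(nz) == 0) stop("empty heat map")
  thr <- mean(nz) + cb$peak_sigma_factor * stats::sd(nz)
  lab <- cpp_label4(NH > thr)
  if (max(lab) == 0) stop("no peaks above threshold")
  nb <- nrow(NH)
  peaks <- list()
  for (k in seq_len(max(lab))) {
    ij <- which(lab == k, arr.ind = TRUE)
    if (nrow(ij) < cb$min_peak_bins) next
    w <- NH[ij]
    ctr <- c(sum((ij[, 1] - 0.5) * w), sum((ij[, 2] - 0.5) * w)) / sum(w) / nb
    peaks[[length(peaks) + 1]] <- list(bins = ij, centroid = ctr)
  }
  if (length(peaks) == 0) stop("no peak region reaches the minimum size")
  peaks
}

# weighted full-covariance EM on binned 2D data
gmm_weighted <- function(xy, w, centers, n_iter = 100, tol = 1e-8) {
  K <- nrow(centers)
  n <- nrow(xy)
  mu <- centers
  sig <- replicate(K, diag(2) * 1e-4, simplify = FALSE)
  pi_k <- rep(1 / K, K)
  loglik_old <- -Inf
  resp <- matrix(0, n, K)
  for (it in seq_len(n_iter)) {
    for (k in seq_len(K)) {
      d <- sweep(xy, 2, mu[k, ])
      si <- solve(sig[[k]])
      q <- rowSums((d %*% si) * d)
      resp[, k] <- pi_k[k] * exp(-q / 2) / (2 * pi * sqrt(det(sig[[k]])))
    }
    tot <- rowSums(resp)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(w * log(tot))
    resp <- resp / tot
    for (k in seq_len(K)) {
      wk <- resp[, k] * w
      sw <- sum(wk)
      pi_k[k] <- sw / sum(w)
      mu[k, ] <- colSums(xy * wk) / sw
      d <- sweep(xy, 2, mu[k, ])
      S <- crossprod(d * wk, d) / sw
      sig[[k]] <- S + diag(2) * 1e-8
    }
    if (abs(ll - loglik_old) < tol * abs(ll)) break
    loglik_old <- ll
  }
  list(mu = mu, sigma = sig, weight = pi_k)
}

#' Extract the red/blue calibration components
#'
#' Fits a Gaussian mixture (one full-covariance component per detected
#' peak, initialized at the peak centroids) to the heat map. The component
#' with the largest mean red chromaticity becomes the red marker ellipse;
#' the one maximizing `1 - r - g` becomes the blue ellipse; the rest
#' (highlights, conversion artefacts) are discarded. Ellipse spreads and
#' rotation come from the eigendecomposition of each component covariance
#' (standard deviations = square roots of the eigenvalues).
#'
#' @param NH heat map matrix.
#' @param peaks result of [find_peaks()].
#' @param cfg pipeline configuration.
#' @return `marker_calibration`.
#' @export
extract_components <- function(NH, peaks, cfg = el_config()) {
  if (length(peaks) < 2) stop("need at least two peaks (red and blue)")
  nb <- nrow(NH)
  idx <- which(NH > 0, arr.ind = TRUE)
  xy <- cbind((idx[, 1] - 0.5) / nb, (idx[, 2] - 0.5) / nb)
  w <- NH[idx]
  centers <- do.call(rbind, lapply(peaks, `[[`, "centroid"))
  fit <- gmm_weighted(xy, w, centers)
  r_comp <- which.max(fit$mu[, 1])
  b_comp <- which.max(1 - fit$mu[, 1] - fit$mu[, 2])
  if (r_comp == b_comp) stop("red and blue components collapsed")
  comp_to_ellipse <- function(k) {
    eg <- eigen(fit$sigma[[k]], symmetric = TRUE)
    s1 <- sqrt(max(eg$values[1], 0)); s2 <- sqrt(max(eg$values[2], 0))
    u1 <- eg$vectors[, 1]
    phi <- if (abs(eg$values[1] - eg$values[2]) < 1e-12) 0 else
      atan2(u1[2], u1[1])
    # keep the angle in (-pi/2, pi/2]; the ellipse is symmetric
    if (phi > pi / 2) phi <- phi - pi
    if (phi <= -pi / 2) phi <- phi + pi
    list(r = fit$mu[k, 1], g = fit$mu[k, 2],
         sigma_r = s1, sigma_g = s2, phi = -phi)
  }
  new_marker_calibration(red = comp_to_ellipse(r_comp),
                         blue = comp_to_ellipse(b_comp))
}

#' Calibrate marker colors from masked chromaticity images
#'
#' Convenience wrapper: heat map, peak detection, component extraction.
#'
#' @inheritParams build_heatmap
#' @return `marker_calibration`.
#' @export
calibrate_marker_colors <- function(chroms, masks, target = gamut_target(),
                                    cfg = el_config()) {
  NH <- build_heatmap(chroms, masks, target, cfg)
  peaks <- find_peaks(NH, cfg)
  extract_components(NH, peaks, cfg)
}
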