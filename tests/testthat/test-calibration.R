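# build a chromaticity "image" (n x 1) from sampled (r, g) pairs
chrom_from_rg <- function(rg, intensity = NULL) {
  keep <- rg[, 1] > 0 & rg[, 2] > 0 & rowSums(rg) < 1
  rg <- rg[keep, , drop = FALSE]
  if (is.null(intensity)) intensity <- runif(nrow(rg), 0.5, 2)
  lin <- array(0, c(nrow(rg), 1, 3))
  lin[, 1, 1] <- rg[, 1] * intensity
  lin[, 1, 2] <- rg[, 2] * intensity
  lin[, 1, 3] <- (1 - rowSums(rg)) * intensity
  to_chromaticity(lin)
}

test_that("the chromaticity heat map localizes planted color clusters", {
  set.seed(9)
  n <- 20000
  rg <- rbind(cbind(rnorm(n, 0.7, 0.03), rnorm(n, 0.1, 0.02)),
              cbind(rnorm(n, 0.1, 0.02), rnorm(n, 0.15, 0.03)))
  ch <- chrom_from_rg(rg)
  NH <- build_heatmap(ch, matrix(TRUE, dim(ch$I)[1], 1))
  # two local maxima near the planted centers (+- 1 bin of 1/256)
  pk <- find_peaks(NH)
  expect_equal(length(pk), 2)
  ctrs <- do.call(rbind, lapply(pk, `[[`, "centroid"))
  ctrs <- ctrs[order(ctrs[, 1]), ]
  expect_equal(ctrs[1, ], c(0.1, 0.15), tolerance = 0.02)
  expect_equal(ctrs[2, ], c(0.7, 0.1), tolerance = 0.02)
  expect_error(build_heatmap(ch, matrix(FALSE, dim(ch$I)[1], 1)))
})

test_that("the median filter suppresses isolated spikes and small blobs are rejected", {
  m <- matrix(0, 64, 64)
  m[30, 30] <- 500                      # isolated single-bin spike
  m[9:13, 9:13] <- 40                   # compact block survives
  f <- electrodecam:::median_filter2(m, 7)
  expect_equal(f[30, 30], 0)
  expect_gt(f[11, 11], 0)

  # a 4-bin blob above threshold does not qualify as a peak
  NH <- matrix(0L, 256, 256)
  NH[cbind(c(40, 40, 41, 41), c(40, 41, 40, 41))] <- 100L
  NH[sample(which(NH == 0), 4000)] <- 1L
  expect_error(find_peaks(NH))
  # a flat nonzero map has no bins above mean + 1.9 sd
  flat <- matrix(3L, 256, 256)
  expect_error(find_peaks(flat))
})

test_that("component extraction recovers planted Gaussians within the stated tolerances", {
  set.seed(41)
  # the red epoxy head covers several times the pixel area of the thin
  # blue rim, so the red component carries more mass. The planted clouds
  # are Gaussians truncated to the chromaticity simplex; their empirical
  # moments are the reference.
  red_cloud <- cbind(rnorm(90000, 0.75, 0.1), rnorm(90000, 0.08, 0.06))
  blue_cloud <- cbind(rnorm(30000, 0.05, 0.02), rnorm(30000, 0.13, 0.06))
  inside <- function(m) m[m[, 1] > 0 & m[, 2] > 0 & rowSums(m) < 1, ]
  red_cloud <- inside(red_cloud); blue_cloud <- inside(blue_cloud)
  ch <- chrom_from_rg(rbind(red_cloud, blue_cloud))
  cal <- calibrate_marker_colors(ch, matrix(TRUE, dim(ch$I)[1], 1))
  expect_lt(abs(cal$red$r - mean(red_cloud[, 1])), 0.01)
  expect_lt(abs(cal$red$g - mean(red_cloud[, 2])), 0.01)
  expect_lt(abs(cal$blue$r - mean(blue_cloud[, 1])), 0.01)
  expect_lt(abs(cal$blue$g - mean(blue_cloud[, 2])), 0.01)
  expect_lt(abs(cal$red$sigma_r / sd(red_cloud[, 1]) - 1), 0.15)
  # the blue component's major axis lies along g: compare the spread pair
  sig <- sort(c(cal$blue$sigma_r, cal$blue$sigma_g))
  ref <- sort(apply(blue_cloud, 2, sd))
  expect_lt(max(abs(sig / ref - 1)), 0.15)
  expect_lt(abs(cal$red$phi) * 180 / pi, 10)

  # round trip: pixels sampled inside the recovered ellipses classify back
  set.seed(43)
  sample_ellipse <- function(e, m = 2000) {
    # spread sigma/3.5 keeps ~99.8 percent of draws inside the unit ellipse
    d1 <- rnorm(m, 0, e$sigma_r / 3.5); d2 <- rnorm(m, 0, e$sigma_g / 3.5)
    cbind(e$r + d1 * cos(e$phi) + d2 * sin(e$phi),
          e$g - d1 * sin(e$phi) + d2 * cos(e$phi))
  }
  cr <- classify_pixels(chrom_from_rg(sample_ellipse(cal$red)), cal)
  cb <- classify_pixels(chrom_from_rg(sample_ellipse(cal$blue)), cal)
  expect_gt(mean(cr$red), 0.99)
  expect_gt(mean(cb$blue), 0.99)
})

test_that("four planted components reduce to red and blue by the selection rules", {
  set.seed(51)
  rg <- rbind(cbind(rnorm(60000, 0.75, 0.06), rnorm(60000, 0.08, 0.04)),
              cbind(rnorm(20000, 0.05, 0.02), rnorm(20000, 0.13, 0.04)),
              cbind(rnorm(15000, 0.42, 0.03), rnorm(15000, 0.40, 0.03)),
              cbind(rnorm(15000, 0.30, 0.02), rnorm(15000, 0.24, 0.02)))
  ch <- chrom_from_rg(rg)
  cal <- calibrate_marker_colors(ch, matrix(TRUE, dim(ch$I)[1], 1))
  expect_lt(abs(cal$red$r - 0.75), 0.03)
  expect_lt(abs(cal$blue$r - 0.05), 0.03)
})
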