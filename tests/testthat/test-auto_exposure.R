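test_that("masked histogram bins by left bisection like explicit gamma compression", {
  tgt <- gamut_target()
  # constant gray image at gamma value 128/255 occupies a single bin
  v <- electrodecam:::srgb_decompress(128 / 255)
  lin <- array(v, c(20, 20, 3))
  h <- masked_histogram(to_chromaticity(lin), matrix(TRUE, 20, 20), tgt)
  expect_equal(sum(h > 0), 1)
  expect_equal(unname(which(h > 0)) - 1L, 128L)

  # oracle: per-pixel gamma compression + flooring
  set.seed(8)
  lin <- array(runif(40 * 40 * 3, 0.02, 0.9), c(40, 40, 3))
  ch <- to_chromaticity(lin)
  mask <- matrix(runif(1600) > 0.3, 40, 40)
  h <- masked_histogram(ch, mask, tgt)
  band <- c(tgt$i_min, tgt$i_max) * 3
  use <- mask & ch$I > band[1] & ch$I < band[2]
  bins <- pmin(floor(electrodecam:::srgb_compress(ch$I[use] / 3) * 256), 255)
  oracle <- tabulate(bins + 1L, 256)
  expect_equal(unname(h), oracle)

  # masked-out bright regions never count
  mask2 <- mask; mask2[1:10, ] <- FALSE
  h2 <- masked_histogram(ch, mask2, tgt)
  expect_lte(sum(h2), sum(h))
  # empty mask is flagged
  h3 <- masked_histogram(ch, matrix(FALSE, 40, 40), tgt)
  expect_true(isTRUE(attr(h3, "empty")))
})

test_that("histogram skewness is the standardized third moment about mid-gray", {
  h <- integer(256)
  h[129 - 10] <- 5; h[129 + 10] <- 5       # symmetric about 128
  expect_equal(histogram_skewness(h), 0)
  h0 <- integer(256); h0[1] <- 7            # all mass at bin 0
  expect_equal(histogram_skewness(h0), -1)
  h2 <- integer(256); h2[1] <- 3; h2[129] <- 1
  v <- c(0, 128); w <- c(3, 1)
  m2 <- sum(w * (v - 128)^2) / 4
  m3 <- sum(w * (v - 128)^3) / 4
  expect_equal(histogram_skewness(h2), m3 / m2^1.5)
  expect_equal(histogram_skewness(integer(256)), 0)
})

test_that("exposure updates move against the skewness and respect the clamps", {
  cfg <- el_config()
  st <- exposure_state(30, cfg)
  cam <- camera_state(tau = 30)
  up0 <- update_exposure(st, cam, 0)
  expect_equal(up0$state$tau_star, 30)
  up_dark <- update_exposure(st, cam, -0.8)
  expect_gt(up_dark$state$tau_star, 30)
  up_bright <- update_exposure(st, cam, 0.8)
  expect_lt(up_bright$state$tau_star, 30)
  expect_true(up_dark$cam$tau <= cfg$exposure$tau_range[2])
  expect_true(up_dark$cam$gain >= cfg$exposure$gain_range[1])
})

test_that("the closed exposure loop reaches a symmetric histogram regardless of background", {
  tgt <- gamut_target()
  set.seed(31)
  fg_tex <- matrix(exp(runif(900, log(0.08), log(1.5))), 30, 30)
  simulate <- function(bg_albedo) {
    # two-zone scene: masked textured foreground + flat background;
    # measured linear intensity is albedo * overall exposure (clipped)
    mask <- matrix(FALSE, 30, 30); mask[8:23, 8:23] <- TRUE
    st <- exposure_state(5)
    cam <- camera_state(tau = 5)
    S <- 1
    for (f in 1:50) {
      expo <- st$tau_star / 40
      lin <- array(0, c(30, 30, 3))
      for (ch in 1:3)
        lin[, , ch] <- pmin(ifelse(mask, fg_tex, bg_albedo) * expo, 1)
      h <- masked_histogram(to_chromaticity(lin), mask, tgt)
      S <- histogram_skewness(h)
      up <- update_exposure(st, cam, S)
      st <- up$state; cam <- up$cam
      if (abs(S) < 0.05) break
    }
    list(S = S, frames = f, level = st$tau_star / 40)
  }
  dim_bg <- simulate(0.1)
  bright_bg <- simulate(0.9)
  expect_lt(abs(dim_bg$S), 0.05)
  expect_lt(abs(bright_bg$S), 0.05)
  expect_lte(dim_bg$frames, 50)
  # steady-state foreground brightness is background-independent
  expect_equal(dim_bg$level, bright_bg$level, tolerance = 0.05)
})
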