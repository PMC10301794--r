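test_that("gain model is 1 at the center temperature and sqrt(2) at the top", {
  g <- gain_model(4500, c(2500, 6500))
  expect_equal(g$gamma_R, 1)
  expect_equal(g$gamma_B, 1)
  expect_equal(gain_model(6500, c(2500, 6500))$gamma_K, sqrt(2))
  expect_equal(gain_model(2501, c(2500, 6500))$gamma_K, sqrt(2 / 4000))
  expect_error(gain_model(2500, c(2500, 6500)))
  # inverse round trip
  for (K in c(3000, 4500, 6000)) {
    gk <- gain_model(K, c(2500, 6500))$gamma_K
    expect_equal(electrodecam:::gain_to_kelvin(gk, c(2500, 6500)), K)
  }
})

test_that("the gain scaler cancels intensity and solves the red/blue ratio", {
  tgt <- gamut_target()
  expect_equal(estimate_scaler(list(r = tgt$r, g = tgt$g, b = tgt$b), tgt), 1)
  for (cc in c(0.5, 1, 2.7)) {   # any normalizer cancels
    expect_equal(estimate_scaler(
      list(r = 2 * tgt$r * cc, g = tgt$g * cc, b = tgt$b * cc), tgt),
      sqrt(1 / 2))
    expect_equal(estimate_scaler(
      list(r = tgt$r * cc, g = tgt$g * cc, b = 2 * tgt$b * cc), tgt),
      sqrt(2))
  }
  expect_true(is.na(estimate_scaler(list(r = 0, g = 0.5, b = 0.5), tgt)))
})

test_that("gamut errors follow the squared-distance definition and accepted updates shrink E", {
  tgt <- gamut_target()
  e0 <- gamut_errors(list(r = tgt$r, g = tgt$g, b = tgt$b), 1, tgt)
  expect_equal(e0$E, 0)
  expect_equal(e0$Estar, 0)
  e1 <- gamut_errors(list(r = 0.463, g = 0.338, b = 0.199), 1, tgt)
  expect_equal(e1$E, 0.02, tolerance = 1e-12)

  # on random reciprocal casts the predicted post-update error improves
  set.seed(7)
  for (k in 1:100) {
    a <- exp(runif(1, -0.25, 0.25))
    rr <- tgt$r * a; bb <- tgt$b / a; gg <- tgt$g
    s <- rr + gg + bb
    est <- list(r = rr / s, g = gg / s, b = bb / s)
    gamma <- estimate_scaler(est, tgt)
    e <- gamut_errors(est, gamma, tgt)
    if (e$E > 1e-12) expect_lt(e$Estar, e$E)
  }
})

test_that("awb_step leaves neutral frames alone and respects the acceptance test", {
  tgt <- gamut_target()
  cfg <- el_config()
  lin <- gray_wall(60, seed = 3)
  ch <- to_chromaticity(lin)
  st <- camera_state(KW = 4500)
  st1 <- awb_step(ch, st, tgt, cfg)
  d <- attr(st1, "awb")
  # jitter-mean error is tiny but nonzero; the step must stay in range
  expect_true(st1$KW >= st1$k_range[1] && st1$KW <= st1$k_range[2])
  # an exactly neutral constant image fails E > threshold: no update
  neutral <- array(0, c(8, 8, 3))
  neutral[, , 1] <- tgt$r; neutral[, , 2] <- tgt$g; neutral[, , 3] <- tgt$b
  st2 <- awb_step(to_chromaticity(neutral), st, tgt, cfg)
  expect_equal(st2$KW, st$KW)
  expect_false(attr(st2, "awb")$updated)
  # no gray pixels: warn and keep state
  red <- array(0, c(8, 8, 3)); red[, , 1] <- 0.9
  expect_warning(st3 <- awb_step(to_chromaticity(red), st, tgt, cfg))
  expect_equal(st3$KW, st$KW)
})

test_that("offline correction is a fixed point on neutral textures and clamps saturation", {
  lin <- gray_wall(80, seed = 13)
  res <- color_correct_offline(lin, 5500)
  expect_lt(max(abs(res$texture - lin)), 0.02)
  expect_equal(res$KW, 5500, tolerance = 0.02)
  expect_error(color_correct_offline(lin, 1500))

  # correcting a shaded recording (illuminant beyond the sensor limit)
  # raises the red gain; a pixel overflowing red saturates in all channels
  px <- gray_wall(40, seed = 1)
  cast <- apply_cast(px, 8000, 6500)
  cast[1, 1, ] <- c(0.9, 0.2, 0.9)
  res2 <- color_correct_offline(cast, 6500)
  expect_gt(res2$KW, 7500)
  expect_equal(as.vector(res2$texture[1, 1, ]), c(1, 1, 1))
})

test_that("closed-loop correction recovers strong casts within the documented error", {
  tgt <- gamut_target()
  lin <- gray_wall(120, seed = 5)
  ch0 <- to_chromaticity(lin)
  for (K in c(2800, 4000, 7000, 8500)) {
    k_rec <- min(max(K, 2500), 6500)
    cast <- apply_cast(lin, K, k_rec)
    res <- color_correct_offline(cast, k_rec, tgt)
    E <- gray_gamut_error(res$texture, tgt)
    expect_lt(E, 1.758e-8)
    ch <- to_chromaticity(res$texture)
    expect_lt(max(abs(ch$r - ch0$r)), 0.01)
    expect_lt(max(abs(ch$b - ch0$b)), 0.01)
  }
})
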