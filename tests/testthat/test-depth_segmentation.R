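test_that("depth smoothing preserves constants and undefined pixels and matches the exact weights", {
  cfg <- el_config()
  d <- matrix(500L, 30, 30)
  sm <- smooth_depth(depth_frame(d), cfg)
  expect_true(all(abs(unclass(sm) - 500) <= 1))
  d[13, 17] <- 0L
  sm2 <- smooth_depth(depth_frame(d), cfg)
  expect_equal(unclass(sm2)[13, 17], 0)

  set.seed(4)
  dr <- matrix(as.integer(400 + 60 * round(matrix(runif(900), 30))), 30, 30)
  tab <- smooth_depth(depth_frame(dr), cfg, exact = FALSE)
  ex <- smooth_depth(depth_frame(dr), cfg, exact = TRUE)
  expect_lte(max(abs(unclass(tab) - unclass(ex))), 1)
})

test_that("edge detection finds large steps as primary edges and ignores small ones", {
  cfg <- el_config()
  flat <- depth_frame(matrix(500L, 40, 40))
  ed <- detect_edges(smooth_depth(flat, cfg), cfg)
  expect_equal(sum(ed$edges), 0)

  d <- matrix(420L, 60, 60); d[, 31:60] <- 1020L
  ed2 <- detect_edges(smooth_depth(depth_frame(d), cfg), cfg)
  cols <- unique(which(ed2$primary, arr.ind = TRUE)[, 2])
  expect_true(length(cols) > 0 && all(cols %in% c(30, 31)))

  d3 <- matrix(420L, 60, 60); d3[, 31:60] <- 425L
  ed3 <- detect_edges(smooth_depth(depth_frame(d3), cfg), cfg)
  expect_equal(sum(ed3$edges), 0)
})

test_that("edge classification matches a brute-force evaluation of the step and minor rules", {
  cfg <- el_config()
  set.seed(12)
  d <- matrix(as.integer(sample(c(0, 400, 406, 420, 800), 40 * 40,
                                replace = TRUE,
                                prob = c(.05, .4, .25, .2, .1))), 40, 40)
  dsm <- smooth_depth(depth_frame(d), cfg)
  ed <- detect_edges(dsm, cfg)
  dm <- unclass(dsm)
  offs <- list(list(c(0, -1), c(0, 1)), list(c(-1, 0), c(1, 0)),
               list(c(-1, -1), c(1, 1)), list(c(-1, 1), c(1, -1)))
  L <- electrodecam:::octagonal_laplacian(dm)
  at <- function(m, r, c) {
    if (r < 1 || r > nrow(m) || c < 1 || c > ncol(m)) 0 else m[r, c]
  }
  for (r in seq(2, 39, by = 3)) for (c in seq(2, 39, by = 3)) {
    if (dm[r, c] == 0) { expect_false(ed$edges[r, c]); next }
    cand <- FALSE; step <- 0
    for (p in offs) {
      la <- at(L, r + p[[1]][1], c + p[[1]][2])
      lb <- at(L, r + p[[2]][1], c + p[[2]][2])
      if (la * lb < 0) cand <- TRUE
      da <- at(dm, r + p[[1]][1], c + p[[1]][2])
      db <- at(dm, r + p[[2]][1], c + p[[2]][2])
      sv <- if (da > 0 && db > 0) abs(da - db)
            else if (da > 0) 2 * abs(da - dm[r, c])
            else if (db > 0) 2 * abs(db - dm[r, c]) else 0
      step <- max(step, sv)
    }
    prim <- cand && step > 12
    minr <- cand && !prim && step > 3.5 &&
      (step > 12 || (step - 3.5) / (12 - step) > 1)
    expect_equal(ed$primary[r, c], prim)
    expect_equal(ed$minor[r, c], minr)
  }
})

test_that("per-row depth band follows the printed min/max/sigma formulas", {
  # constant rows collapse the band onto the constant
  b <- electrodecam:::depth_band(rep(420, 8), rep(420, 8), 200)
  expect_equal(unname(b), c(420, 420))
  b2 <- electrodecam:::depth_band(rep(150, 8), rep(150, 8), 200)
  expect_equal(unname(b2[1]), 200)   # clamped at the closest valid depth

  set.seed(3)
  for (k in 1:20) {
    rc <- runif(12, 300, 600)
    rf <- rc + runif(12, 0, 300)
    b <- electrodecam:::depth_band(rc, rf, 200)
    d_far <- min(max(rf) + (max(rf) - min(rc)) / 3, mean(rf) + 3 * sd(rf))
    d_close <- max(min(rc) - (max(rc) - min(rc)) / 3,
                   mean(rc) - 3 * sd(rf), 200)
    expect_equal(unname(b), c(d_close, d_far))
  }
})

test_that("patient selection keeps the central component and drops small blobs", {
  cfg <- el_config()
  d <- matrix(900L, 90, 90); d[25:65, 30:60] <- 420L
  seg <- segment_depth(depth_frame(d), cfg)
  expect_false(is.null(seg))
  # mask is the rectangle interior (minus its edge ring), never edge pixels
  expect_true(all(which(seg$mask, arr.ind = TRUE)[, 1] %in% 25:65))
  expect_true(all(which(seg$mask, arr.ind = TRUE)[, 2] %in% 30:60))
  expect_gt(sum(seg$mask), 1000)
  expect_false(any(seg$mask & seg$edges))
  expect_true(all(unclass(depth_frame(d))[seg$mask] > 0))

  d2 <- matrix(0L, 60, 60); d2[28:33, 28:35] <- 400L   # 48 px < 200
  expect_null(segment_depth(depth_frame(d2), cfg))
})
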