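test_that("the dominant normal averages a tight bundle and rejects degeneracy", {
  n <- c(0, 0.6, 0.8)
  bundle <- matrix(rep(n, 50), ncol = 3, byrow = TRUE)
  expect_equal(dominant_normal(bundle), n, tolerance = 1e-12)

  set.seed(5)
  tilt <- 5 * pi / 180
  pert <- t(sapply(1:200, function(i) {
    ax <- rnorm(3); ax <- ax - sum(ax * n) * n
    ax <- ax / sqrt(sum(ax^2))
    a <- runif(1, -tilt, tilt)
    cos(a) * n + sin(a) * ax
  }))
  nm <- dominant_normal(pert)
  expect_lt(acos(min(sum(nm * n), 1)) * 180 / pi, 1)

  opposing <- rbind(matrix(rep(c(0, 0, 1), 20), ncol = 3, byrow = TRUE),
                    matrix(rep(c(0, 0, -1), 20), ncol = 3, byrow = TRUE))
  expect_error(dominant_normal(opposing))
  expect_error(dominant_normal(matrix(0, 10, 3)))
})

test_that("the disk/ring model fit recovers centers from full and partial markers", {
  cfg <- el_config()
  ctr <- c(10, -5, 3)
  nrm <- c(0.2, -0.3, 0.93); nrm <- nrm / sqrt(sum(nrm^2))
  full <- make_marker_cluster(center = ctr, normal = nrm)
  f <- fit_marker(full, cfg)
  expect_lt(sqrt(sum((f$X - ctr)^2)), 0.1)

  half <- make_marker_cluster(center = ctr, normal = nrm, arc = pi)
  f2 <- fit_marker(half, cfg)
  # a 180-degree arc at the ring mid-radius biases the center toward the
  # arc by about the radial offset times 2/pi (~1 mm for this geometry)
  expect_lt(sqrt(sum((f2$X - ctr)^2)), 1.2)

  # coincident points cannot define a circle
  flat <- make_marker_cluster(center = ctr)
  flat$points <- matrix(rep(ctr, 60), ncol = 3, byrow = TRUE)
  flat$normals <- flat$normals[1:60, ]
  flat$color <- flat$color[1:60]
  expect_null(fit_marker(flat, cfg))
})

test_that("split markers merge through mutual nearest neighbours, distinct markers do not", {
  cfg <- el_config()
  base <- make_marker_cluster(center = c(0, 0, 0))
  # a shadow along the disk/ring boundary splits the marker into a pure
  # red piece and a pure blue piece
  mk <- function(sel) structure(list(points = base$points[sel, , drop = FALSE],
                                     normals = base$normals[sel, , drop = FALSE],
                                     color = base$color[sel],
                                     view = base$view[sel]),
                                class = "electrode_cluster")
  pieces <- list(mk(base$color == "blue"), mk(base$color == "red"))
  ratios <- sapply(pieces, function(p)
    sum(p$color == "red") / max(sum(p$color == "blue"), 1))
  expect_true(any(ratios <= 1 / 3 | ratios >= 3))
  merged <- merge_split_clusters(pieces, cfg)
  expect_length(merged, 1)
  f <- fit_marker(merged[[1]], cfg)
  expect_lt(sqrt(sum((f$X - c(0, 0, 0))^2)), 1.5)

  # two complete markers two head-diameters apart stay separate
  a <- make_marker_cluster(center = c(0, 0, 0))
  b <- make_marker_cluster(center = c(28, 0, 0))
  expect_length(merge_split_clusters(list(a, b), cfg), 2)
})

test_that("ball pivoting builds the two patches and leaves singles unconnected", {
  cfg <- el_config()
  s <- 32
  fx <- as.vector(outer(1:8, rep(1, 4))) * s
  fz <- as.vector(outer(rep(1, 8), 1:4)) * s
  centers <- tibble::tibble(
    x = c(fx, fx, -80, 380, 380),
    y = c(rep(-100, 32), rep(100, 32), -50, -50, -50),
    z = c(fz, fz, 160, 160, -60))
  g <- build_grid(centers, cfg)
  tab <- table(g$component)
  expect_equal(as.integer(tab[names(tab) == "0"]), 3)
  expect_equal(sort(as.integer(tab[names(tab) != "0"])), c(32, 32))
  # mean 9-NN spacing reflects the grid pitch
  expect_gt(g$xbar, s)
  expect_lt(g$xbar, 2 * s)

  # near-duplicate centers collapse onto the grid
  dup <- rbind(centers, centers[1, ] + c(1, 0.5, 0.5))
  g2 <- build_grid(dup, cfg)
  expect_equal(nrow(g2$centers), nrow(centers))
})

test_that("channel labels follow the frontal/dorsal scan order and singles classify by position", {
  cfg <- el_config()
  model <- make_torso()
  tru <- ground_truth(model)
  # feed the true centers (frontal frame) to grid + labeling directly
  centers <- tibble::tibble(x = tru$x, y = tru$y, z = tru$z - 250)
  g <- build_grid(centers, cfg)
  map <- assign_labels(g, cfg)
  expect_equal(nrow(map), 67)
  expect_false(any(is.na(map$label)))
  j <- match(round(centers$x, 6), round(tru$x, 6))
  expect_equal(map$label, tru$label[j])
  expect_equal(sum(map$patch == "frontal"), 32)
  expect_equal(sum(map$patch == "dorsal"), 30)
  expect_equal(sum(map$patch == "single"), 5)

  ev <- evaluate_positions(map, dplyr_free_truth <- tibble::tibble(
    label = tru$label, x = tru$x, y = tru$y, z = tru$z))
  expect_equal(ev$mean_error, 0, tolerance = 1e-6)
  expect_true(all(ev$per_electrode$label_correct))
})
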