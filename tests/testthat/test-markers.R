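test_that("pixel classification equals the rotated-ellipse membership test", {
  calib <- default_marker_calibration()
  mk <- function(r, g) {
    lin <- array(0, c(1, 1, 3))
    lin[1, 1, ] <- c(r, g, 1 - r - g) * 0.8
    to_chromaticity(lin)
  }
  expect_true(classify_pixels(mk(0.75, 0.08), calib)$red[1, 1])
  n <- classify_pixels(mk(1 / 3, 1 / 3), calib)
  expect_false(n$red[1, 1] || n$blue[1, 1])
  expect_true(classify_pixels(mk(0.05, 0.13), calib)$blue[1, 1])

  # brute-force oracle over random chromaticities
  set.seed(17)
  rg <- cbind(runif(1e4, 0, 1), runif(1e4, 0, 1))
  rg <- rg[rowSums(rg) < 0.999, ]
  lin <- array(0, c(nrow(rg), 1, 3))
  lin[, 1, 1] <- rg[, 1] * 0.7
  lin[, 1, 2] <- rg[, 2] * 0.7
  lin[, 1, 3] <- (1 - rowSums(rg)) * 0.7
  cls <- classify_pixels(to_chromaticity(lin), calib)
  inside <- function(rgm, e) {
    dr <- rgm[, 1] - e$r; dg <- rgm[, 2] - e$g
    (dr * cos(e$phi) - dg * sin(e$phi))^2 / e$sigma_r^2 +
      (dr * sin(e$phi) + dg * cos(e$phi))^2 / e$sigma_g^2 <= 1
  }
  red_b <- inside(rg, calib$red)
  blue_b <- inside(rg, calib$blue) & !red_b
  expect_identical(as.vector(cls$red), red_b)
  expect_identical(as.vector(cls$blue), blue_b)

  # a zero rotation angle reduces to the axis-aligned ellipse
  e0 <- calib$red; e0$phi <- 0
  d0 <- (rg[, 1] - e0$r)^2 / e0$sigma_r^2 + (rg[, 2] - e0$g)^2 / e0$sigma_g^2
  expect_identical(inside(rg, e0), d0 <= 1)
})

test_that("marker pixels lift through barycentric coordinates onto the surface", {
  surf <- surface_full()
  # a pixel exactly at a uv vertex lifts to that vertex
  vid <- which.min(abs(surf$uv[, 1] - round(surf$uv[, 1])) +
                   abs(surf$uv[, 2] - round(surf$uv[, 2])))
  uvq <- matrix(round(surf$uv[vid, ]), 1)
  out <- lift_to_surface(uvq, surf)
  if (nrow(out) == 1) {
    expect_lt(sqrt(sum((c(out$x, out$y, out$z) - surf$vertices[vid, ])^2)), 2)
  }
  # round trip: lifted points reproject to the query pixel within 0.5 px
  set.seed(23)
  q <- cbind(runif(200, min(surf$uv[, 1]) + 5, max(surf$uv[, 1]) - 5),
             runif(200, min(surf$uv[, 2]) + 5, max(surf$uv[, 2]) - 5))
  lf <- lift_to_surface(q, surf)
  expect_gt(nrow(lf), 100)
  tr <- surf$triangles
  loc <- electrodecam:::cpp_locate_uv(q[, 1], q[, 2],
                                      matrix(surf$uv[tr, 1], ncol = 3),
                                      matrix(surf$uv[tr, 2], ncol = 3))
  hit <- which(loc$tri > 0)
  # reproject via barycentric interpolation of uv itself
  ti <- loc$tri[hit]
  b <- loc$bary[hit, , drop = FALSE]
  uv2 <- b[, 1] * surf$uv[tr[ti, 1], ] + b[, 2] * surf$uv[tr[ti, 2], ] +
         b[, 3] * surf$uv[tr[ti, 3], ]
  expect_lt(max(abs(uv2 - q[hit, ])), 0.5)
})

test_that("the opposite-color filter removes isolated blobs and boundary stragglers", {
  cl <- make_marker_cluster(center = c(0, 0, 0))
  cloud <- tibble::tibble(x = cl$points[, 1], y = cl$points[, 2],
                          z = cl$points[, 3],
                          nx = 0, ny = 0, nz = 1,
                          color = cl$color, view = 1L)
  kept <- opposite_color_filter(cloud)
  expect_equal(nrow(kept), nrow(cloud))   # ideal marker: everything kept

  # isolated red blob (no blue anywhere near): removed entirely
  blob <- cloud
  blob$x <- blob$x + ifelse(blob$color == "red", 500, 0)
  kept2 <- opposite_color_filter(blob)
  expect_equal(sum(kept2$color == "red"), 0)

  # a blue point just beyond the ring width from all reds: removed
  far_blue <- cloud[1, ]
  far_blue$color <- "blue"
  far_blue$x <- max(cloud$x[cloud$color == "red"]) + 2 + 0.05
  far_blue$y <- 0; far_blue$z <- 0
  test_cloud <- rbind(cloud[cloud$color == "red", ], far_blue)
  kept3 <- opposite_color_filter(test_cloud)
  expect_equal(sum(kept3$color == "blue"), 0)
})

test_that("density clustering recovers planted markers and rejects uniform noise", {
  cfg <- el_config()
  set.seed(29)
  lay <- expand.grid(x = seq(0, 3) * 40, z = seq(0, 1) * 40)   # 8 markers
  clusters <- lapply(seq_len(nrow(lay)), function(i)
    make_marker_cluster(center = c(lay$x[i], 0, lay$z[i])))
  cloud <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    tibble::tibble(x = cl$points[, 1] + rnorm(nrow(cl$points), 0, 0.5),
                   y = cl$points[, 2] + rnorm(nrow(cl$points), 0, 0.5),
                   z = cl$points[, 3] + rnorm(nrow(cl$points), 0, 0.5),
                   nx = 0, ny = 0, nz = 1, color = cl$color, view = 1L)
  }))
  out <- cluster_markers(cloud, n_el = 8, cfg)
  expect_length(out, 8)

  # pipeline parameters on uniform noise yield no clusters
  set.seed(12)
  noise <- cbind(runif(300, 0, 300), runif(300, 0, 300), runif(300, 0, 300))
  lab <- hdbscan_cluster(noise, min_cluster_size = 20, min_samples = 20,
                         eps_split = 7)
  expect_equal(length(setdiff(unique(lab), 0L)), 0)

  # well-separated Gaussian blobs are each one cluster
  set.seed(7)
  ctrs <- cbind(runif(12, 0, 200), runif(12, 0, 200), 0)
  while (min(dist(ctrs)) < 40)
    ctrs <- cbind(runif(12, 0, 200), runif(12, 0, 200), 0)
  pts <- do.call(rbind, lapply(1:12, function(i)
    sweep(matrix(rnorm(60 * 3, 0, 2), ncol = 3), 2, ctrs[i, ], "+")))
  lab2 <- hdbscan_cluster(pts, 20, 10, 0)
  expect_equal(length(setdiff(unique(lab2), 0L)), 12)
})

test_that("frontal realignment recovers a yaw applied to a symmetric torso cloud", {
  model <- make_torso()
  al <- seq(-pi, pi, length.out = 220)[-1]
  zz <- seq(10, 490, length.out = 90)
  grid <- expand.grid(alpha = al, z = zz)
  pts <- electrodecam:::torso_point(model, grid$alpha, grid$z)
  T0 <- realign_frontal(pts)
  yaw0 <- atan2(T0[2, 1], T0[1, 1])
  for (phi in c(15, -20)) {
    Rz <- electrodecam:::rot_z(phi * pi / 180)
    Ty <- realign_frontal(pts %*% t(Rz))
    yaw <- atan2(Ty[2, 1], Ty[1, 1])
    rec <- (yaw - yaw0) * 180 / pi
    rec <- ((rec + 180) %% 360) - 180
    expect_equal(rec, -phi, tolerance = 1)
  }
})
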