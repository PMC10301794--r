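test_that("pair initialization estimates the relative z-rotation from shoulder medians", {
  ss <- surfaces_small()
  c1 <- surface_cloud(ss$surfs[[1]])
  # identical surfaces: zero rotation, near-identity transform
  ini0 <- init_pair(c1, c1)
  expect_equal(ini0$dphi, 0, tolerance = 1e-9)
  expect_lt(max(abs(ini0$T0 - diag(4))), 1e-6)
  expect_gt(ini0$lc_min, 0)

  # the same surface rotated 20 degrees about z
  Rz <- electrodecam:::rot_z(20 * pi / 180)
  c2 <- list(points = c1$points %*% t(Rz),
             normals = c1$normals %*% t(Rz))
  ini <- init_pair(c2, c1)   # target = rotated, source = original
  expect_equal(ini$dphi * 180 / pi, 20, tolerance = 2)

  # nearest-neighbour spacing reflects the sampling pitch
  expect_lt(ini0$lc_min, 3 * el_config()$registration$voxel)
})

test_that("self-registration is exact and known transforms are recovered", {
  surf <- surface_full()
  c1 <- surface_cloud(surf)
  res0 <- symmetric_icp(c1, c1)
  expect_lt(res0$rmse, 1e-6)
  expect_lt(rotation_angle_deg(res0$T4[1:3, 1:3]), 1e-4)

  set.seed(3)
  Ttrue <- rigid_transform(electrodecam:::rot_z(25 * pi / 180),
                           c(8, -15, 24))
  c2 <- list(points = transform_points(Ttrue, c1$points) +
               matrix(rnorm(length(c1$points), 0, 1), ncol = 3),
             normals = electrodecam:::transform_dirs(Ttrue, c1$normals))
  res <- symmetric_icp(c2, c1)   # recovers source(c1) -> target(c2)
  Rerr <- res$T4[1:3, 1:3] %*% t(Ttrue[1:3, 1:3])
  expect_lt(rotation_angle_deg(Rerr), 0.5)
  perr <- transform_points(res$T4, c1$points) -
          transform_points(Ttrue, c1$points)
  expect_lt(mean(sqrt(rowSums(perr^2))), 1)
  # the correspondence-distance schedule tightened
  expect_lt(res$lc_final, res$lc_init)
})

test_that("forward and reverse registrations are mutually inverse", {
  surf <- surface_full()
  c1 <- surface_cloud(surf)
  set.seed(9)
  Ttrue <- rigid_transform(electrodecam:::rot_z(12 * pi / 180), c(5, -8, 12))
  c2 <- list(points = transform_points(Ttrue, c1$points) +
               matrix(rnorm(length(c1$points), 0, 0.5), ncol = 3),
             normals = electrodecam:::transform_dirs(Ttrue, c1$normals))
  ab <- symmetric_icp(c2, c1)
  ba <- symmetric_icp(c1, c2)
  comp <- ab$T4 %*% ba$T4
  expect_lt(rotation_angle_deg(comp[1:3, 1:3]) * pi / 180, 1e-3)
  expect_lt(sqrt(sum(comp[1:3, 4]^2)), 1)
})

test_that("cross-view registration aligns consecutive canonicalized views", {
  ss <- surfaces_small()
  res <- symmetric_icp(ss$surfs[[1]], ss$surfs[[2]])
  expect_false(is.null(res))
  # ground-truth relative transform from the known poses
  P <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  A_of <- function(i) {
    p <- ss$poses[[i]]
    M <- P %*% t(p$R)
    rigid_transform(M, as.vector(-M %*% p$center) -
                      c(0, attr(ss$surfs[[i]], "origin_shift"), 0))
  }
  Ttrue <- A_of(1) %*% solve(A_of(2))
  src <- surface_cloud(ss$surfs[[2]])
  perr <- transform_points(res$T4, src$points) -
          transform_points(Ttrue, src$points)
  expect_lt(mean(sqrt(rowSums(perr^2))), 3)
})

test_that("global chaining composes pairwise transforms and flags breaks", {
  shift <- rigid_transform(diag(3), c(5, 0, 0))
  pr <- structure(list(T4 = shift, rmse = 0.5), class = "registration_result")
  g <- chain_global(list(pr))
  expect_equal(g[[2]], shift)
  g2 <- chain_global(list(pr, pr))
  expect_equal(g2[[3]][1, 4], 10)
  id <- structure(list(T4 = diag(4), rmse = 0), class = "registration_result")
  g3 <- chain_global(list(id, id, id))
  for (k in 1:4) expect_equal(unclass(g3[[k]]), diag(4),
                              ignore_attr = TRUE)
  g4 <- chain_global(list(pr, NULL, pr))
  expect_false(isTRUE(attr(g4[[3]], "aligned")))
  expect_false(isTRUE(attr(g4[[4]], "aligned")))
})
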