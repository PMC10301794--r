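# Shared fixtures, built once per test run. Scenes are rendered at reduced
# resolution where marker detection is not under test.

.cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# full-resolution single view of the default 67-electrode torso
view_full <- function() {
  memo("view_full", function() {
    model <- make_torso()
    cam <- default_camera()
    poses <- default_poses(model, n_views = 14)
    v <- render_views(model, poses[1], cam, k_true = 6000,
                      depth_sigma = 1, seed = 11)[[1]]
    list(model = model, cam = cam, pose = poses[[1]], view = v)
  })
}

# full-resolution single view meshed and canonicalized
surface_full <- function() {
  memo("surface_full", function() {
    vf <- view_full()
    s <- depth_to_mesh(vf$view$depth, segment_depth(vf$view$depth), vf$cam)
    s <- remove_occluded(s)
    s <- remove_degenerate_and_skinny(s)
    canonicalize(s)
  })
}

# three consecutive reduced-resolution views, meshed and canonicalized
surfaces_small <- function() {
  memo("surfaces_small", function() {
    model <- make_torso()
    cam <- default_camera(width = 160, height = 213)
    poses <- default_poses(model, n_views = 14)
    views <- render_views(model, poses[1:3], cam, k_true = 5500,
                          depth_sigma = 1, seed = 21)
    surfs <- lapply(views, function(vw) {
      s <- depth_to_mesh(vw$depth, segment_depth(vw$depth), cam)
      s <- remove_occluded(s)
      s <- remove_degenerate_and_skinny(s)
      canonicalize(s)
    })
    list(model = model, cam = cam, poses = poses[1:3], surfs = surfs)
  })
}

# deterministic disk+ring marker cluster (points exactly on the model)
make_marker_cluster <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                                arc = 2 * pi, ring_radius = 6,
                                n_red = 150, n_blue = 120) {
  u <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- u - sum(u * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  th_r <- (seq_len(n_red) * 2.399963) %% (2 * pi)   # golden-angle spiral
  rr <- sqrt(seq(0.02, 0.98, length.out = n_red)) * 5
  red <- outer(rr * cos(th_r), e1) + outer(rr * sin(th_r), e2)
  th_b <- seq(0, arc, length.out = n_blue + 1)[-1]
  blue <- outer(ring_radius * cos(th_b), e1) +
          outer(ring_radius * sin(th_b), e2)
  pts <- sweep(rbind(red, blue), 2, center, "+")
  structure(list(points = pts,
                 normals = matrix(rep(normal, nrow(pts)), ncol = 3,
                                  byrow = TRUE),
                 color = c(rep("red", n_red), rep("blue", n_blue)),
                 view = rep(1L, nrow(pts))),
            class = "electrode_cluster")
}

# apply an illuminant/recording color cast through the sensor gain model
apply_cast <- function(lin, k_true, k_rec, k_range = c(2000, 9000)) {
  gK <- gain_model(k_true, k_range)$gamma_K
  gR <- gain_model(k_rec, k_range)$gamma_K
  out <- lin
  out[, , 1] <- lin[, , 1] * gR / gK
  out[, , 3] <- lin[, , 3] * gK / gR
  pmin(pmax(out, 0), 1)
}

# gray-wall test image: neutral chromaticity with red-blue jitter
gray_wall <- function(n = 120, seed = 5) {
  set.seed(seed)
  e <- pmin(pmax(stats::rnorm(n * n, 0, 0.03), -0.07), 0.07)
  I <- stats::runif(n * n, 0.9, 2.2)
  lin <- array(0, c(n, n, 3))
  lin[, , 1] <- matrix((0.363 + e) * I, n)
  lin[, , 2] <- matrix(0.338 * I, n)
  lin[, , 3] <- matrix((0.299 - e) * I, n)
  lin
}

# gamut error of the mean gray-pixel chromaticity of a linear image
gray_gamut_error <- function(lin, target = gamut_target()) {
  ch <- to_chromaticity(lin)
  sel <- select_gray_pixels(ch, target)
  if (!any(sel)) return(Inf)
  (mean(ch$r[sel]) - target$r)^2 + (mean(ch$g[sel]) - target$g)^2 +
    (mean(ch$b[sel]) - target$b)^2
}

rotation_angle_deg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}
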