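# Synthetic torso scenes with known electrode ground truth. The torso is an
# elliptic cylinder with a smooth low-amplitude radial modulation (stand-in
# for body-surface relief), carrying red-disk/blue-ring markers at known
# positions. Views are rendered by analytic ray casting from a depth sensor
# and a laterally offset color sensor, with per-view illuminant color casts
# applied through the same gain model the white-balancing stage assumes,
# plus depth noise and quantization.

# elliptic angle parameterization: surface point at (alpha, z).
# Two ingredients make the shape body-like enough for the geometry stages:
# incommensurate relief harmonics (wavelengths ~110/70/45 mm) standing in
# for muscle/rib body-surface relief (they lock registration in z and
# azimuth), and an ellipsoidal shoulder dome above ~84% height that gives
# the shoulder-median logic a real anatomical feature to latch onto.
torso_radial <- function(model, alpha, z) {
  a <- model$mod_amp
  relief <- 1 + a *
    (0.5 * sin(model$mod_k_alpha * alpha) * cos(2 * pi * z / 110) +
     0.3 * sin((model$mod_k_alpha + 2) * alpha + 1.1) *
       cos(2 * pi * z / 70 + 0.6) +
     0.2 * sin(2 * alpha + 0.5) * cos(2 * pi * z / 45 + 1.2))
  zs <- 0.72 * model$height
  ch <- 0.30 * model$height
  dome <- ifelse(z > zs, sqrt(pmax(1 - ((z - zs) / ch)^2, 0.2)), 1)
  relief * dome
}

torso_point <- function(model, alpha, z) {
  m <- torso_radial(model, alpha, z)
  cbind(model$rx * m * cos(alpha), model$ry * m * sin(alpha), z)
}

torso_normal <- function(model, alpha, z) {
  # numeric gradient of F = (x/rx)^2 + (y/ry)^2 - m(alpha,z)^2
  p <- torso_point(model, alpha, z)
  eps <- 1e-3
  Fv <- function(q) {
    al <- atan2(q[, 2] / model$ry, q[, 1] / model$rx)
    (q[, 1] / model$rx)^2 + (q[, 2] / model$ry)^2 -
      torso_radial(model, al, q[, 3])^2
  }
  n <- sapply(1:3, function(k) {
    dp <- matrix(0, nrow(p), 3); dp[, k] <- eps
    (Fv(p + dp) - Fv(p - dp)) / (2 * eps)
  })
  if (is.null(dim(n))) n <- matrix(n, ncol = 3)
  n / sqrt(rowSums(n^2))
}

# cumulative arc length s(alpha) of the base ellipse, and its inverse
arc_tables <- function(model, n = 4096) {
  al <- seq(-pi, pi, length.out = n)
  dx <- -model$rx * sin(al); dy <- model$ry * cos(al)
  ds <- sqrt(dx^2 + dy^2)
  s <- c(0, cumsum((ds[-1] + ds[-n]) / 2 * diff(al)))
  list(alpha = al, s = s)
}

alpha_at_arc <- function(tab, s0) {
  stats::approx(tab$s, tab$alpha, xout = s0, rule = 2)$y
}

arc_at_alpha <- function(tab, a0) {
  stats::approx(tab$alpha, tab$s, xout = a0, rule = 2)$y
}

# electrode layouts: tibble(channel, label, patch, alpha, z)
electrode_layout <- function(model, n_el) {
  tab <- arc_tables(model)
  grid_patch <- function(center_deg, n_cols, n_rows, z0, spacing, patch,
                         first_channel, row_order, col_order) {
    ac <- center_deg * pi / 180
    s0 <- arc_at_alpha(tab, ac)
    cols <- (seq_len(n_cols) - (n_cols + 1) / 2) * spacing
    rows <- z0 + (seq_len(n_rows) - 1) * spacing
    out <- NULL
    ch <- first_channel
    for (r in if (row_order == "bottom_up") seq_len(n_rows) else rev(seq_len(n_rows))) {
      cseq <- if (col_order == "alpha_up") seq_len(n_cols) else rev(seq_len(n_cols))
      for (cidx in cseq) {
        out <- rbind(out, data.frame(
          channel = ch, label = as.character(ch), patch = patch,
          alpha = alpha_at_arc(tab, s0 + cols[cidx]), z = rows[r]))
        ch <- ch + 1
      }
    }
    out
  }
  single <- function(ch, label, alpha_deg, z) {
    data.frame(channel = ch, label = label, patch = "single",
               alpha = alpha_deg * pi / 180, z = z)
  }
  lay <- if (n_el == 67) {
    rbind(
      # frontal 8x4, ascending bottom-right to top-left
      grid_patch(-90, 8, 4, 260, 32, "frontal", 1, "bottom_up", "alpha_up"),
      # dorsal 6x5, continuing top-right to bottom-left
      grid_patch(90, 6, 5, 240, 32, "dorsal", 33, "top_down", "alpha_down"),
      single(63, "RA", -135, 450),
      single(64, "LA", -45, 450),
      single(65, "LL", -45, 50),
      single(66, "AUX_R_FRONT", -165, 140),
      single(67, "AUX_R_BACK", 155, 180)
    )
  } else if (n_el == 32) {
    rbind(grid_patch(-90, 4, 4, 260, 32, "frontal", 1, "bottom_up", "alpha_up"),
          grid_patch(90, 4, 4, 240, 32, "dorsal", 17, "top_down", "alpha_down"))
  } else if (n_el == 8) {
    grid_patch(-90, 4, 2, 280, 32, "frontal", 1, "bottom_up", "alpha_up")
  } else {
    stop("no layout defined for n_el = ", n_el)
  }
  lay
}

#' Build a ground-truth torso model
#'
#' Elliptic-cylinder torso with red-disk/blue-ring electrode markers at
#' known positions and channel labels.
#'
#' @param n_el electrode count; layouts exist for 67 (frontal 8x4 patch,
#'   dorsal 6x5 patch, 3 Einthoven and 2 right-side singles), 32 and 8.
#' @param height,rx,ry torso dimensions (mm).
#' @param mod_amp,mod_k_alpha relative amplitude and base angular frequency
#'   of the surface relief modulation.
#' @param disc_radius,ring_width marker geometry (mm).
#' @return object of class `torso_model` with an `electrodes` tibble
#'   (channel, label, patch, position `x`,`y`,`z`, normal `nx`,`ny`,`nz`).
#' @export
make_torso <- function(n_el = 67, height = 500, rx = 160, ry = 105,
                       mod_amp = 0.03, mod_k_alpha = 3,
                       disc_radius = 5, ring_width = 2) {
  model <- list(height = height, rx = rx, ry = ry, mod_amp = mod_amp,
                mod_k_alpha = mod_k_alpha,
                disc_radius = disc_radius, ring_width = ring_width)
  lay <- electrode_layout(model, n_el)
  pos <- torso_point(model, lay$alpha, lay$z)
  nrm <- torso_normal(model, lay$alpha, lay$z)
  el <- tibble::tibble(channel = lay$channel, label = lay$label,
                       patch = lay$patch,
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
  dmin <- min(stats::dist(pos))
  if (dmin < 2 * (disc_radius + ring_width))
    stop("electrode layout has overlapping markers (min spacing ",
         round(dmin, 1), " mm)")
  model$electrodes <- el
  structure(model, class = "torso_model")
}

#' Camera poses around the torso
#'
#' @param model `torso_model`.
#' @param n_views number of views.
#' @param span_deg total azimuthal coverage (degrees); views run from the
#'   patient's right-front around the left side to the right-back.
#' @param distance camera distance from the torso axis (mm).
#' @param jitter logical; add small pose perturbations.
#' @param seed RNG seed for the jitter.
#' @return list of poses; each has the camera `center` (world, mm) and
#'   rotation `R` (columns: camera x right, y down, z viewing, in world
#'   coordinates).
#' @export
default_poses <- function(model, n_views = 14, span_deg = 270,
                          distance = 550, jitter = TRUE, seed = 1234) {
  set.seed(seed)
  th <- seq(-45, -45 + span_deg, length.out = n_views) * pi / 180
  lapply(th, function(t) {
    d <- distance + if (jitter) stats::runif(1, -15, 15) else 0
    zc <- model$height / 2 + if (jitter) stats::runif(1, -10, 10) else 0
    t <- t + if (jitter) stats::runif(1, -2, 2) * pi / 180 else 0
    center <- c(d * sin(t), -d * cos(t), zc)
    R <- cbind(c(cos(t), sin(t), 0),     # camera x
               c(0, 0, -1),              # camera y (image down)
               c(-sin(t), cos(t), 0))    # camera z (viewing)
    list(center = center, R = R, theta = t)
  })
}

# ray cast one camera against the scene; returns list(z = depth matrix (mm,
# NA = miss), hit = world coords of hits, hit_idx = linear pixel indices,
# on_torso = logical)
raycast <- function(model, center, R, intr, wall_dist) {
  W <- intr$width; H <- intr$height
  u <- rep(seq_len(W), each = H); v <- rep(seq_len(H), W)
  dir_cam <- cbind((u - intr$cx) / intr$fx, (v - intr$cy) / intr$fy, 1)
  dir <- dir_cam %*% t(R)   # world direction; t = camera z-depth
  ox <- center[1]; oy <- center[2]; oz <- center[3]
  A <- (dir[, 1] / model$rx)^2 + (dir[, 2] / model$ry)^2
  B <- 2 * (ox * dir[, 1] / model$rx^2 + oy * dir[, 2] / model$ry^2)
  C <- (ox / model$rx)^2 + (oy / model$ry)^2 - 1
  disc <- B^2 - 4 * A * C
  t0 <- ifelse(disc >= 0, (-B - sqrt(pmax(disc, 0))) / (2 * A), NA)
  t0[!is.na(t0) & t0 <= 0] <- NA
  # Newton refinement onto the modulated surface
  g <- function(tt) {
    px <- ox + tt * dir[, 1]; py <- oy + tt * dir[, 2]; pz <- oz + tt * dir[, 3]
    al <- atan2(py / model$ry, px / model$rx)
    (px / model$rx)^2 + (py / model$ry)^2 - torso_radial(model, al, pz)^2
  }
  tt <- t0
  ok <- !is.na(tt)
  if (any(ok)) {
    for (it in 1:8) {
      gv <- rep(NA_real_, length(tt)); gv[ok] <- g(tt)[ok]
      dt <- 0.5
      gd <- rep(NA_real_, length(tt))
      gd[ok] <- (g(tt + dt)[ok] - g(tt - dt)[ok]) / (2 * dt)
      step <- ifelse(abs(gd) > 1e-12, gv / gd, 0)
      tt[ok] <- tt[ok] - pmin(pmax(step[ok], -30), 30)
    }
    # reject rays that did not converge onto the surface (grazing the
    # shoulder dome) or left the valid height range
    gv <- rep(NA_real_, length(tt)); gv[ok] <- g(tt)[ok]
    tt[ok][abs(gv[ok]) > 1e-3 | tt[ok] <= 0] <- NA
  }
  pz <- oz + tt * dir[, 3]
  tt[!is.na(tt) & (pz < 0 | pz > model$height)] <- NA
  on_torso <- !is.na(tt)
  tt[is.na(tt)] <- wall_dist
  z <- matrix(tt, H, W)
  hit <- cbind(ox + tt * dir[, 1], oy + tt * dir[, 2], oz + tt * dir[, 3])
  list(z = z, hit = hit, on_torso = matrix(on_torso, H, W), dir = dir)
}

# linear RGB color of scene points (n x 3 world coords)
scene_colors <- function(model, pts, on_torso, view_dir, marker_gain) {
  n <- nrow(pts)
  chrom <- matrix(0, n, 3)
  inten <- numeric(n)
  el <- model$electrodes
  if (any(on_torso)) {
    tp <- pts[on_torso, , drop = FALSE]
    # nearest marker distance
    dmin <- rep(Inf, nrow(tp)); didx <- rep(1L, nrow(tp))
    for (j in seq_len(nrow(el))) {
      dj <- sqrt((tp[, 1] - el$x[j])^2 + (tp[, 2] - el$y[j])^2 +
                 (tp[, 3] - el$z[j])^2)
      upd <- dj < dmin
      didx[upd] <- j
      dmin[upd] <- dj[upd]
    }
    r_out <- model$disc_radius + model$ring_width
    red <- dmin <= model$disc_radius
    blue <- dmin > model$disc_radius & dmin <= r_out
    skin <- !red & !blue
    cm <- matrix(rep(c(0.45, 0.32, 0.23), each = nrow(tp)), nrow(tp), 3)
    if (any(red))
      cm[red, ] <- matrix(c(0.75, 0.08, 0.17), sum(red), 3, byrow = TRUE)
    if (any(blue))
      cm[blue, ] <- matrix(c(0.05, 0.13, 0.82), sum(blue), 3, byrow = TRUE)
    # headlight shading; chromaticity is unaffected
    al <- atan2(tp[, 2] / model$ry, tp[, 1] / model$rx)
    nrm <- cbind(cos(al) / model$rx, sin(al) / model$ry, 0)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    cosv <- pmax(-rowSums(nrm * view_dir[on_torso, , drop = FALSE]), 0.1)
    ii <- ifelse(red | blue, 0.75, 1.15) * (0.55 + 0.45 * cosv)
    ii <- ii * ifelse(red | blue, marker_gain[didx], 1)
    chrom[on_torso, ] <- cm
    inten[on_torso] <- ii
  }
  if (any(!on_torso)) {
    nw <- sum(!on_torso)
    e <- pmin(pmax(stats::rnorm(nw, 0, 0.03), -0.07), 0.07)
    chrom[!on_torso, ] <- cbind(0.363 + e, 0.338, 0.299 - e)
    wp <- pts[!on_torso, , drop = FALSE]
    inten[!on_torso] <- 1.5 + 0.45 * sin(wp[, 3] / 120) * cos(wp[, 1] / 150)
  }
  chrom * inten
}

#' Render synthetic views of a torso scene
#'
#' Z-buffer-equivalent analytic depth render plus a color render from a
#' laterally offset color viewpoint (so occlusion handling is exercised).
#' Each view gets an illuminant color cast applied through the inverse of
#' the white-balance gain model at the view's color temperature, sensor
#' noise, gamma compression to 8 bits, and millimetre depth quantization
#' with an invalid band at large depth discontinuities.
#'
#' @param model `torso_model`.
#' @param poses list of poses from [default_poses()].
#' @param camera `camera_model`; the default matches a scaled-down
#'   short-range depth/color sensor pair in portrait mode.
#' @param k_true per-view illuminant color temperatures (K); recycled.
#' @param depth_sigma depth noise standard deviation (mm).
#' @param color_sigma linear-domain color noise standard deviation.
#' @param wall_dist distance of the background wall from the camera (mm).
#' @param seed RNG seed.
#' @return list of views: each has `depth` (`depth_frame`), `color` (8-bit
#'   gamma RGB array), `k_true`, `k_recorded` (illuminant clamped to the
#'   sensor range, emulating the online controller), and the `pose`.
#' @export
render_views <- function(model, poses, camera = default_camera(),
                         k_true = 5500, depth_sigma = 1, color_sigma = 0.01,
                         wall_dist = 1100, seed = 1234) {
  set.seed(seed)
  k_true <- rep(k_true, length.out = length(poses))
  sensor_range <- c(2500, 6500)
  virtual_range <- c(2000, 9000)
  marker_gain <- stats::runif(nrow(model$electrodes), 0.85, 1.15)
  views <- vector("list", length(poses))
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    depth_in_range <- sqrt(sum((p$center[1:2])^2)) - max(model$rx, model$ry)
    if (depth_in_range < 200 || depth_in_range > 1500)
      stop("pose ", i, " outside the valid depth range")
    rc_d <- raycast(model, p$center, p$R, camera$depth, wall_dist)
    # color camera: offset along camera x
    cc <- p$center + as.vector(p$R %*% camera$baseline)
    rc_c <- raycast(model, cc, p$R, camera$color, wall_dist)
    vd <- rc_c$dir / sqrt(rowSums(rc_c$dir^2))
    lin <- scene_colors(model, rc_c$hit, as.vector(rc_c$on_torso), -vd,
                        marker_gain)
    # illuminant cast relative to the neutral setting through the gain model
    k_rec <- min(max(k_true[i], sensor_range[1]), sensor_range[2])
    g_set <- gain_model(k_rec, virtual_range)$gamma_K
    g_ill <- gain_model(k_true[i], virtual_range)$gamma_K
    lin[, 1] <- lin[, 1] * g_set / g_ill
    lin[, 3] <- lin[, 3] * g_ill / g_set
    if (color_sigma > 0)
      lin <- lin + stats::rnorm(length(lin), 0, color_sigma)
    lin <- pmin(pmax(lin, 0), 1)
    H <- camera$color$height; W <- camera$color$width
    col8 <- array(0L, c(H, W, 3))
    for (ch in 1:3) col8[, , ch] <- matrix(gamma_compress8(lin[, ch]), H, W)

    z <- rc_d$z
    if (depth_sigma > 0) z <- z + matrix(stats::rnorm(length(z), 0, depth_sigma),
                                         nrow(z))
    z <- round(z)
    # invalid band at large discontinuities (silhouette shadowing)
    jump <- (abs(z - shift_mat(z, 0, 1)) > 150) |
            (abs(z - shift_mat(z, 0, -1)) > 150) |
            (abs(z - shift_mat(z, 1, 0)) > 150) |
            (abs(z - shift_mat(z, -1, 0)) > 150)
    z[jump] <- 0
    views[[i]] <- list(depth = depth_frame(z, camera$depth),
                       color = col8,
                       k_true = k_true[i], k_recorded = k_rec,
                       pose = p)
  }
  views
}

#' Default scaled-down camera model for synthetic scenes
#'
#' Portrait-mode pinhole pair: 320 x 426 px, 54 degree horizontal field of
#' view, color sensor offset 25 mm to the right of the depth sensor.
#'
#' @param width,height image size (px).
#' @param hfov horizontal field of view (degrees).
#' @param baseline_x color-sensor offset along camera x (mm).
#' @return `camera_model`.
#' @export
default_camera <- function(width = 320, height = 426, hfov = 54,
                           baseline_x = 25) {
  intr <- pinhole_intrinsics(width, height, hfov)
  camera_model(intr, intr, baseline = c(baseline_x, 0, 0))
}

#' Ground-truth electrode table of a model
#'
#' @param model `torso_model`.
#' @return tibble of channels, labels, patches, positions and normals.
#' @export
ground_truth <- function(model) model$electrodes
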