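# Electrode marker extraction: red/blue pixel classification in corrected
# chromaticity textures, barycentric lifting onto the 3D surface,
# opposite-color proximity filtering, density clustering into per-electrode
# point sets, and frontal-plane realignment of the merged cloud.

# rotated-ellipse membership test on chromaticity planes
ellipse_member <- function(r, g, ell, sigma_squared = TRUE) {
  p <- if (sigma_squared) 2 else 1
  dr <- r - ell$r; dg <- g - ell$g
  cphi <- cos(ell$phi); sphi <- sin(ell$phi)
  (dr * cphi - dg * sphi)^2 / ell$sigma_r^p +
    (dr * sphi + dg * cphi)^2 / ell$sigma_g^p <= 1
}

#' Classify marker pixels by chromaticity
#'
#' A pixel is red when it falls inside the calibrated rotated red ellipse
#' in (r, g) chromaticity space, blue analogously; red wins when the
#' ellipses overlap.
#'
#' @param chrom `chromaticity` image (from a color-corrected texture).
#' @param calib `marker_calibration`.
#' @param cfg pipeline configuration.
#' @return list of logical matrices `red` and `blue`.
#' @export
classify_pixels <- function(chrom, calib = default_marker_calibration(),
                            cfg = el_config()) {
  sq <- cfg$color$ellipse_sigma_squared
  red <- chrom$defined & ellipse_member(chrom$r, chrom$g, calib$red, sq)
  blue <- chrom$defined & ellipse_member(chrom$r, chrom$g, calib$blue, sq) & !red
  list(red = red, blue = blue)
}

#' Lift classified pixels onto the 3D surface
#'
#' Finds the uv triangle containing each marker pixel and maps it to 3D by
#' its barycentric coordinates; pixels outside every triangle are dropped.
#'
#' @param pixels list with logical matrices `red`/`blue` on the texture
#'   grid (as from [classify_pixels()]), or a two-column matrix of (u, v)
#'   coordinates.
#' @param surface `textured_surface` with uv coordinates.
#' @param view integer view id carried through to the output.
#' @return tibble marker cloud: `x`, `y`, `z`, `nx`, `ny`, `nz`, `color`,
#'   `view`.
#' @export
lift_to_surface <- function(pixels, surface, view = 1L) {
  if (is.list(pixels) && !is.null(pixels$red)) {
    ridx <- which(pixels$red, arr.ind = TRUE)
    bidx <- which(pixels$blue, arr.ind = TRUE)
    uvq <- rbind(cbind(ridx[, 2], ridx[, 1]), cbind(bidx[, 2], bidx[, 1]))
    cols <- c(rep("red", nrow(ridx)), rep("blue", nrow(bidx)))
  } else {
    uvq <- pixels
    cols <- rep("red", nrow(uvq))
  }
  if (nrow(uvq) == 0)
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          nx = numeric(0), ny = numeric(0), nz = numeric(0),
                          color = character(0), view = integer(0)))
  tr <- surface$triangles
  uv <- surface$uv
  loc <- cpp_locate_uv(uvq[, 1], uvq[, 2],
                       matrix(uv[tr, 1], ncol = 3),
                       matrix(uv[tr, 2], ncol = 3))
  hit <- loc$tri > 0
  if (!any(hit))
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          nx = numeric(0), ny = numeric(0), nz = numeric(0),
                          color = character(0), view = integer(0)))
  vn <- vertex_normals(surface)
  ti <- loc$tri[hit]
  b <- loc$bary[hit, , drop = FALSE]
  v <- surface$vertices
  pt <- b[, 1] * v[tr[ti, 1], , drop = FALSE] +
        b[, 2] * v[tr[ti, 2], , drop = FALSE] +
        b[, 3] * v[tr[ti, 3], , drop = FALSE]
  nr <- b[, 1] * vn[tr[ti, 1], , drop = FALSE] +
        b[, 2] * vn[tr[ti, 2], , drop = FALSE] +
        b[, 3] * vn[tr[ti, 3], , drop = FALSE]
  nr <- nr / pmax(sqrt(rowSums(nr^2)), 1e-12)
  tibble::tibble(x = pt[, 1], y = pt[, 2], z = pt[, 3],
                 nx = nr[, 1], ny = nr[, 2], nz = nr[, 3],
                 color = cols[hit], view = as.integer(view))
}

#' Opposite-color proximity filter
#'
#' Keeps red points only when a blue point lies within the clip-head
#' radius, and blue points only when a red point lies within the ring
#' width: isolated single-color blobs (cables, reflections) are removed.
#'
#' @param cloud marker cloud tibble.
#' @param rho_red radius for red points (clip-head outer radius, mm).
#' @param rho_blue radius for blue points (ring width, mm).
#' @param cfg pipeline configuration supplying the defaults.
#' @return filtered marker cloud.
#' @export
opposite_color_filter <- function(cloud,
                                  rho_red = NULL, rho_blue = NULL,
                                  cfg = el_config()) {
  mk <- cfg$marker
  if (is.null(rho_red)) rho_red <- mk$disc_radius + mk$ring_width
  if (is.null(rho_blue)) rho_blue <- mk$ring_width
  red <- cloud$color == "red"
  rp <- as.matrix(cloud[red, c("x", "y", "z")])
  bp <- as.matrix(cloud[!red, c("x", "y", "z")])
  if (nrow(rp) == 0 || nrow(bp) == 0) return(cloud[integer(0), ])
  keep_r <- cpp_has_neighbor_within(rp, bp, rho_red)
  keep_b <- cpp_has_neighbor_within(bp, rp, rho_blue)
  keep <- logical(nrow(cloud))
  keep[red] <- keep_r
  keep[!red] <- keep_b
  cloud[keep, ]
}

#' Cluster a marker cloud into per-electrode point sets
#'
#' Hierarchical density clustering with a minimum cluster size of
#' `max(n_red / (4 * n_clip), min_samples)`, the configured minimum sample
#' count, and a split-stopping distance equal to the clip-head outer
#' radius. Noise points are discarded.
#'
#' @param cloud filtered marker cloud tibble.
#' @param n_el expected electrode (clip) count.
#' @param cfg pipeline configuration.
#' @return list of `electrode_cluster` objects (fields `points`, `normals`,
#'   `color`).
#' @export
cluster_markers <- function(cloud, n_el = NULL, cfg = el_config()) {
  mk <- cfg$marker
  if (is.null(n_el)) n_el <- mk$n_electrodes
  if (nrow(cloud) == 0) {
    warning("empty marker cloud")
    return(list())
  }
  n_red <- sum(cloud$color == "red")
  nc_min <- max(ceiling(n_red / (4 * n_el)), mk$min_samples)
  eps_split <- mk$disc_radius + mk$ring_width
  pts <- as.matrix(cloud[, c("x", "y", "z")])
  labels <- hdbscan_cluster(pts, min_cluster_size = nc_min,
                            min_samples = mk$min_samples,
                            eps_split = eps_split)
  ids <- setdiff(sort(unique(labels)), 0L)
  if (length(ids) == 0) {
    warning("no marker clusters found")
    return(list())
  }
  lapply(ids, function(k) {
    sel <- labels == k
    structure(list(points = pts[sel, , drop = FALSE],
                   normals = as.matrix(cloud[sel, c("nx", "ny", "nz")]),
                   color = cloud$color[sel],
                   view = cloud$view[sel]),
              class = "electrode_cluster")
  })
}

#' Realign the merged torso cloud with the frontal plane
#'
#' Splits the cloud into chest/belly/hip thirds along z, the chest into
#' three lateral sections, and rotates about z so the vector between the
#' median points of the outer (shoulder) sections aligns with the x-axis.
#' Refined over a few passes.
#'
#' @param pts N x 3 merged surface point matrix (patient frame).
#' @return 4x4 rigid transform (rotation about z).
#' @export
realign_frontal <- function(pts) {
  T4 <- diag(4)
  cur <- pts
  for (it in 1:12) {
    zr <- range(cur[, 3])
    chest <- cur[cur[, 3] > zr[1] + 2 / 3 * diff(zr), , drop = FALSE]
    if (nrow(chest) < 30) {
      warning("degenerate shoulder sections; returning identity")
      return(diag(4))
    }
    g <- cut(rank(chest[, 1], ties.method = "first"), 3, labels = FALSE)
    if (length(unique(g)) < 3) {
      warning("degenerate shoulder sections; returning identity")
      return(diag(4))
    }
    mr <- apply(chest[g == 1, , drop = FALSE], 2, stats::median)
    ml <- apply(chest[g == 3, , drop = FALSE], 2, stats::median)
    h <- ml - mr
    ang <- atan2(h[2], h[1])
    R <- rot_z(-ang)
    T4 <- rigid_transform(R) %*% T4
    cur <- cur %*% t(R)
    if (abs(ang) < 0.5 * pi / 180) break
  }
  T4
}
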