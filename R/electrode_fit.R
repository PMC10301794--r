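# Fitting the planar red-disk/blue-ring marker model to clusters, merging
# split markers, building the electrode grid by ball pivoting, and
# assigning ECG channel labels.

#' Dominant normal of a cluster's normal bundle
#'
#' Rank-truncated singular decomposition of the per-point surface normals:
#' singular directions within three decades of the leading one are kept and
#' the unit-normalized mean of the truncated reconstruction is returned.
#'
#' @param normals N x 3 matrix of unit normals.
#' @return unit 3-vector.
#' @export
dominant_normal <- function(normals) {
  stopifnot(nrow(normals) >= 3)
  if (all(abs(normals) < 1e-12)) stop("degenerate normal bundle (all zero)")
  sv <- svd(normals)
  keep <- sv$d >= sv$d[1] * 1e-3
  rec <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  m <- colMeans(rec)
  len <- sqrt(sum(m^2))
  if (len < 1e-6) stop("ambiguous normal bundle (opposing normals)")
  m / len
}

#' Fit the planar disk/ring marker model to a cluster
#'
#' Projects the cluster points onto the plane through their centroid with
#' the dominant normal, then minimizes
#' `sum_blue (rho - rho_disc)^2 + sum_{red, rho > rho_disc} (rho - rho_disc)^2
#'  + <X - centroid, n>^2`
#' over the center X with a bounded quasi-Newton (L-BFGS-B) search started
#' at the centroid.
#'
#' @param cluster `electrode_cluster`.
#' @param cfg pipeline configuration (`marker` geometry).
#' @return list with `X` (center, mm), `normal`, `residual`, `n_points`;
#'   `NULL` when the cluster is degenerate or the fit fails.
#' @export
fit_marker <- function(cluster, cfg = el_config()) {
  mk <- cfg$marker
  pts <- if (!is.null(cluster$fit_points)) cluster$fit_points else cluster$points
  cols <- if (!is.null(cluster$fit_color)) cluster$fit_color else cluster$color
  if (nrow(pts) < 5) return(NULL)
  nm <- tryCatch(dominant_normal(cluster$normals), error = function(e) NULL)
  if (is.null(nm)) return(NULL)
  ctr <- colMeans(pts)
  off <- as.vector((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% nm)
  proj <- pts - outer(off, nm)
  spread <- max(apply(proj, 2, function(x) diff(range(x))))
  if (spread < 1) return(NULL)   # coincident points: no circle to fit
  is_blue <- cols == "blue"
  rho_disc <- mk$disc_radius
  obj <- function(X) {
    d <- sqrt((proj[, 1] - X[1])^2 + (proj[, 2] - X[2])^2 +
              (proj[, 3] - X[3])^2)
    pen_b <- sum((d[is_blue] - rho_disc)^2)
    dr <- d[!is_blue]
    pen_r <- sum(pmax(dr - rho_disc, 0)^2)
    pen_b + pen_r + sum((X - ctr) * nm)^2
  }
  lim <- 2 * (mk$disc_radius + mk$ring_width)
  res <- tryCatch(
    stats::optim(ctr, obj, method = "L-BFGS-B",
                 lower = ctr - lim, upper = ctr + lim,
                 control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(res) || res$convergence != 0) return(NULL)
  list(X = res$par, normal = nm, residual = res$value, n_points = nrow(pts))
}

#' Merge clusters that are pieces of one split marker
#'
#' Clusters whose red/blue count ratio is out of balance are split
#' candidates; two candidates merge when at least 10 points of each have
#' their nearest out-of-cluster neighbour in the other. The model is
#' subsequently fitted to the larger piece only.
#'
#' @param clusters list of `electrode_cluster`.
#' @param cfg pipeline configuration.
#' @return possibly shorter list of clusters.
#' @export
merge_split_clusters <- function(clusters, cfg = el_config()) {
  nk <- length(clusters)
  if (nk < 2) return(clusters)
  ratio <- vapply(clusters, function(cl) {
    nr <- sum(cl$color == "red"); nb <- sum(cl$color == "blue")
    if (nb == 0) Inf else nr / nb
  }, numeric(1))
  cand <- which(ratio <= 1 / 3 | ratio >= 3)
  if (length(cand) < 2) return(clusters)
  all_pts <- do.call(rbind, lapply(clusters, `[[`, "points"))
  all_id <- rep(seq_along(clusters), vapply(clusters, function(cl)
    nrow(cl$points), integer(1)))
  mutual <- function(a, b) {
    pa <- clusters[[a]]$points
    other <- all_pts[all_id != a, , drop = FALSE]
    oid <- all_id[all_id != a]
    nn <- cpp_nn1(pa, other)
    sum(oid[nn$idx] == b) >= 10
  }
  merged_into <- seq_len(nk)
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (i >= j) next
    a <- cand[i]; b <- cand[j]
    if (merged_into[a] != a || merged_into[b] != b) next
    if (mutual(a, b) && mutual(b, a)) {
      ca <- clusters[[a]]; cb <- clusters[[b]]
      big <- if (nrow(ca$points) >= nrow(cb$points)) ca else cb
      m <- structure(list(points = rbind(ca$points, cb$points),
                          normals = rbind(ca$normals, cb$normals),
                          color = c(ca$color, cb$color),
                          view = c(ca$view, cb$view),
                          fit_points = big$points,
                          fit_color = big$color),
                     class = "electrode_cluster")
      clusters[[a]] <- m
      merged_into[b] <- a
    }
  }
  clusters[merged_into == seq_len(nk)]
}

# circumcenter and circumradius of a 3D triangle
circum3 <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
  den <- 2 * (uu * vv - uv^2)
  if (abs(den) < 1e-12) return(NULL)
  a <- (vv * (uu - uv)) / den
  b <- (uu * (vv - uv)) / den
  ctr <- p1 + a * u + b * v
  list(center = ctr, radius = sqrt(sum((ctr - p1)^2)))
}

# ball-pivoting triangulation by triple enumeration with an empty-ball test
ball_pivot <- function(X, radii) {
  n <- nrow(X)
  if (n < 3) return(matrix(integer(0), 0, 3))
  D <- as.matrix(stats::dist(X))
  tris <- NULL
  rmax <- max(radii)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) {
    if (D[i, j] > 2 * rmax) next
    for (k in (j + 1):n) {
      if (D[i, k] > 2 * rmax || D[j, k] > 2 * rmax) next
      cc <- circum3(X[i, ], X[j, ], X[k, ])
      if (is.null(cc)) next
      ok <- FALSE
      for (rho in radii) {
        if (cc$radius > rho) next
        h <- sqrt(max(rho^2 - cc$radius^2, 0))
        e1 <- X[j, ] - X[i, ]; e2 <- X[k, ] - X[i, ]
        nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
                 e1[3] * e2[1] - e1[1] * e2[3],
                 e1[1] * e2[2] - e1[2] * e2[1])
        nrm <- nrm / sqrt(sum(nrm^2))
        others <- setdiff(seq_len(n), c(i, j, k))
        if (length(others) == 0) { ok <- TRUE; break }
        op <- X[others, , drop = FALSE]
        for (sgn in c(1, -1)) {
          bc <- cc$center + sgn * h * nrm
          d2 <- (op[, 1] - bc[1])^2 + (op[, 2] - bc[2])^2 + (op[, 3] - bc[3])^2
          if (min(d2) >= (rho * (1 - 1e-9))^2) { ok <- TRUE; break }
        }
        if (ok) break
      }
      if (ok) tris <- rbind(tris, c(i, j, k))
    }
  }
  if (is.null(tris)) matrix(integer(0), 0, 3) else tris
}

# swap vertical edges that cross the horizontal line between the common
# neighbours of their endpoints (grid normalization)
normalize_grid_edges <- function(X, tris) {
  if (nrow(tris) < 2) return(tris)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
  keys <- ekey(edges[, 1], edges[, 2])
  tri_ids <- rep(seq_len(nrow(tris)), 3)
  for (key in unique(keys[duplicated(keys)])) {
    ts <- unique(tri_ids[keys == key])
    if (length(ts) != 2) next
    ab <- as.integer(strsplit(key, " ")[[1]])
    cds <- setdiff(as.vector(tris[ts, ]), ab)
    if (length(cds) != 2) next
    a <- ab[1]; b <- ab[2]; cc <- cds[1]; dd <- cds[2]
    za <- X[a, 3]; zb <- X[b, 3]; zc <- X[cc, 3]; zd <- X[dd, 3]
    vert_ab <- abs(za - zb)
    if (vert_ab > abs(zc - zd) * 1.5 &&
        min(za, zb) < (zc + zd) / 2 && (zc + zd) / 2 < max(za, zb)) {
      tris[ts[1], ] <- c(cc, dd, a)
      tris[ts[2], ] <- c(cc, dd, b)
    }
  }
  tris
}

#' Build the electrode grid from fitted marker centers
#'
#' Triangulates the centers by ball pivoting (radii `xbar/2` and `xbar`
#' from the mean 9-nearest-neighbour spacing, with outliers excluded from
#' that statistic), collapses near-duplicate centers (closer than 2/3 of
#' the clip-head radius; the one attached to the larger connected group is
#' retained), normalizes vertical grid edges, and splits the result into
#' the two largest connected patches (frontal/dorsal) plus unconnected
#' single electrodes.
#'
#' @param centers tibble/data frame with `x`, `y`, `z` (and optionally
#'   `nx`, `ny`, `nz`) of fitted centers.
#' @param cfg pipeline configuration.
#' @return list with `centers` (possibly reduced), `triangles`,
#'   `component` (per center: 1 frontal-candidate, 2 second patch,
#'   0 single), `xbar`.
#' @export
build_grid <- function(centers, cfg = el_config()) {
  mk <- cfg$marker
  X <- as.matrix(centers[, c("x", "y", "z")])
  stopifnot(nrow(X) >= 4)
  rho0 <- mk$disc_radius + mk$ring_width
  repeat {
    n <- nrow(X)
    k9 <- min(9, n - 1)
    kd <- cpp_knn_dist(X, k9)
    x9 <- rowMeans(kd)
    ok <- x9 <= mean(x9) + 2 * stats::sd(x9)
    xbar <- mean(x9[ok])
    tris <- ball_pivot(X, c(xbar / 2, xbar))
    comp <- rep(0L, n)
    if (nrow(tris) > 0) {
      parent <- seq_len(n)
      findp <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (t in seq_len(nrow(tris))) {
        a <- findp(tris[t, 1])
        for (v in tris[t, 2:3]) parent[findp(v)] <- a
      }
      roots <- vapply(seq_len(n), findp, integer(1))
      comp <- match(roots, unique(roots))
    }
    # collapse centers closer than 2/3 of the clip-head radius
    D <- as.matrix(stats::dist(X))
    diag(D) <- Inf
    close_pair <- which(D < 2 / 3 * rho0, arr.ind = TRUE)
    if (nrow(close_pair) == 0) break
    pr <- close_pair[1, ]
    sizes <- table(comp)
    keep_first <- sizes[as.character(comp[pr[1]])] >=
      sizes[as.character(comp[pr[2]])]
    drop_i <- if (keep_first) pr[2] else pr[1]
    X <- X[-drop_i, , drop = FALSE]
    centers <- centers[-drop_i, , drop = FALSE]
    if (nrow(X) < 4) break
  }
  tris <- normalize_grid_edges(X, tris)
  # two largest connected meshes = electrode patches
  comp_sizes <- table(comp[comp > 0])
  patch_ids <- as.integer(names(sort(comp_sizes, decreasing = TRUE)))
  patch_ids <- patch_ids[seq_len(min(2, length(patch_ids)))]
  singles <- vapply(seq_len(nrow(X)), function(i) {
    sz <- sum(comp == comp[i])
    sz < 3 || !(comp[i] %in% patch_ids)
  }, logical(1))
  grp <- integer(nrow(X))
  if (length(patch_ids) >= 1) grp[comp == patch_ids[1] & !singles] <- 1L
  if (length(patch_ids) >= 2) grp[comp == patch_ids[2] & !singles] <- 2L
  if (sum(grp > 0) == 0 || length(unique(grp[grp > 0])) < 2)
    warning("fewer than two connected electrode patches found")
  list(centers = centers, triangles = tris, component = grp, xbar = xbar)
}

# split sorted coordinates into rows: gaps larger than half the dominant
# pitch (with a 10 mm floor) separate rows
row_split <- function(z) {
  o <- order(z)
  d <- diff(z[o])
  thr <- max(10, if (length(d) > 0) max(d) / 2 else 0)
  grp <- cumsum(c(1, as.integer(d > thr)))
  out <- integer(length(z))
  out[o] <- grp
  out
}

#' Assign ECG channel labels to the electrode map
#'
#' Frontal patch channels are numbered ascending from bottom-right to
#' top-left (rows bottom to top, each stored right to left); the dorsal
#' patch continues from top-right to bottom-left. Singles are classified
#' as the Einthoven electrodes (right/left shoulder, left hip) and the two
#' right-side auxiliaries by their position in the frontal-plane frame.
#'
#' @param grid result of [build_grid()], in the realigned frontal frame
#'   (+x patient right to left, -y anterior, +z up).
#' @param cfg pipeline configuration.
#' @return `electrode_map` tibble: `channel`, `label`, `patch`, `x`, `y`,
#'   `z` (plus normals when present). Unclassifiable electrodes get label
#'   `NA`.
#' @export
assign_labels <- function(grid, cfg = el_config()) {
  X <- as.matrix(grid$centers[, c("x", "y", "z")])
  grp <- grid$component
  n <- nrow(X)
  # identify frontal vs dorsal by mean y (anterior = -y)
  ids <- sort(unique(grp[grp > 0]))
  if (length(ids) == 2) {
    my <- vapply(ids, function(g) mean(X[grp == g, 2]), numeric(1))
    frontal_id <- ids[which.min(my)]
    dorsal_id <- setdiff(ids, frontal_id)
  } else if (length(ids) == 1) {
    frontal_id <- ids
    dorsal_id <- integer(0)
  } else {
    frontal_id <- integer(0); dorsal_id <- integer(0)
  }
  channel <- rep(NA_integer_, n)
  label <- rep(NA_character_, n)
  patch <- rep("single", n)
  ch <- 1L
  if (length(frontal_id) == 1) {
    idx <- which(grp == frontal_id)
    patch[idx] <- "frontal"
    rows <- row_split(X[idx, 3])
    for (r in sort(unique(rows))) {             # bottom to top
      ri <- idx[rows == r]
      ri <- ri[order(X[ri, 1])]                 # right (-x) to left (+x)
      channel[ri] <- seq(ch, ch + length(ri) - 1L)
      ch <- ch + length(ri)
    }
  }
  if (length(dorsal_id) == 1) {
    idx <- which(grp == dorsal_id)
    patch[idx] <- "dorsal"
    rows <- row_split(X[idx, 3])
    for (r in rev(sort(unique(rows)))) {        # top to bottom
      ri <- idx[rows == r]
      ri <- ri[order(X[ri, 1])]
      channel[ri] <- seq(ch, ch + length(ri) - 1L)
      ch <- ch + length(ri)
    }
  }
  label[!is.na(channel)] <- as.character(channel[!is.na(channel)])
  # singles: Einthoven + right-side auxiliaries. Directions are taken
  # relative to the electrode centroid and the frontal patch (robust to a
  # residual yaw of the frontal-plane realignment and to the origin
  # sitting off the torso axis).
  sing <- which(grp == 0)
  if (length(sing) > 0) {
    ctr <- colMeans(X)
    if (length(frontal_id) == 1) {
      fdir <- colMeans(X[grp == frontal_id, , drop = FALSE]) - ctr
    } else {
      fdir <- c(0, -1, 0)
    }
    fdir[3] <- 0
    fdir <- fdir / max(sqrt(sum(fdir^2)), 1e-9)
    ldir <- c(-fdir[2], fdir[1], 0)          # z x f: patient right-to-left
    zr <- range(X[, 3]); zmid <- mean(zr); zspan <- diff(zr)
    res <- lapply(sing, function(i) {
      p <- X[i, ] - ctr
      to_left <- sum(p * ldir); to_front <- sum(p * fdir)
      if (X[i, 3] > zmid + 0.25 * zspan) {
        if (to_left < 0) "RA" else "LA"
      } else if (X[i, 3] < zmid - 0.25 * zspan && to_left > 0) {
        "LL"
      } else if (to_front > 0) "AUX_R_FRONT" else "AUX_R_BACK"
    })
    sl <- unlist(res)
    order_map <- c(RA = 1L, LA = 2L, LL = 3L, AUX_R_FRONT = 4L, AUX_R_BACK = 5L)
    for (nm in names(order_map)) {
      hit <- sing[sl == nm]
      if (length(hit) == 1) {
        label[hit] <- nm
        channel[hit] <- ch + order_map[[nm]] - 1L
      }
    }
    ch <- ch + 5L
  }
  out <- tibble::tibble(channel = channel, label = label, patch = patch,
                        x = X[, 1], y = X[, 2], z = X[, 3])
  if (all(c("nx", "ny", "nz") %in% names(grid$centers))) {
    out$nx <- grid$centers$nx; out$ny <- grid$centers$ny
    out$nz <- grid$centers$nz
  }
  class(out) <- c("electrode_map", class(out))
  out
}

#' Compare an electrode map against ground truth
#'
#' Joins on labels, rigidly aligns the estimate to the truth (the global
#' registration frame is arbitrary), and reports per-electrode positional
#' errors plus label correctness (after alignment, the nearest true
#' electrode of each estimate must carry its own label).
#'
#' @param est `electrode_map`.
#' @param truth ground-truth tibble with `label`, `x`, `y`, `z`.
#' @return list with `per_electrode` tibble (`label`, `error`,
#'   `label_correct`), `mean_error`, `sd_error`, `n_matched`, `n_truth`.
#' @export
evaluate_positions <- function(est, truth) {
  est <- est[!is.na(est$label), ]
  m <- match(truth$label, est$label)
  matched <- !is.na(m)
  A <- as.matrix(est[m[matched], c("x", "y", "z")])
  B <- as.matrix(truth[matched, c("x", "y", "z")])
  if (sum(matched) >= 3) {
    T4 <- kabsch(A, B)
    A_all <- transform_points(T4, as.matrix(est[, c("x", "y", "z")]))
    A2 <- A_all[m[matched], , drop = FALSE]
  } else {
    T4 <- diag(4)
    A_all <- as.matrix(est[, c("x", "y", "z")])
    A2 <- A
  }
  err <- sqrt(rowSums((A2 - B)^2))
  # label correctness: nearest truth electrode of each aligned estimate
  nn <- cpp_nn1(A_all, as.matrix(truth[, c("x", "y", "z")]))
  nearest_lab <- truth$label[nn$idx]
  lab_ok_all <- nearest_lab == est$label
  per <- tibble::tibble(label = truth$label[matched], error = err,
                        label_correct = lab_ok_all[m[matched]])
  list(per_electrode = per,
       mean_error = mean(err), sd_error = stats::sd(err),
       n_matched = sum(matched), n_truth = nrow(truth),
       n_est = nrow(est), transform = T4)
}

# least-squares rigid alignment A -> B (Kabsch)
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cb - as.vector(R %*% ca))
}

#' @export
print.electrode_map <- function(x, ...) {
  cat(sprintf("Electrode map: %d electrodes (%d frontal, %d dorsal, %d single)\n",
              nrow(x), sum(x$patch == "frontal"), sum(x$patch == "dorsal"),
              sum(x$patch == "single")))
  NextMethod()
}

#' Plot an electrode map
#'
#' Front/back projections of the labeled electrode positions.
#'
#' @param object `electrode_map`.
#' @param ... unused.
#' @return ggplot object.
#' @export
autoplot.electrode_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$side <- ifelse(df$y <= 0, "front (y < 0)", "back (y > 0)")
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = z, color = patch)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = label),
                       size = 2.5, vjust = -1, show.legend = FALSE) +
    ggplot2::facet_wrap(~side) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, right to left)", y = "z (mm, up)",
                  color = "patch")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

utils::globalVariables(c("x", "z", "patch", "label", "side"))
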