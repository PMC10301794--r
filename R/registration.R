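# Multi-view surface registration: symmetric point-to-plane ICP with an
# adaptive correspondence-distance schedule, median-shoulder rotation
# initialization, and chaining of pairwise transforms into a global frame.

#' Rigid transform utilities
#'
#' `rigid_transform` builds a 4x4 homogeneous matrix from a rotation and
#' translation; `transform_points` applies one to an N x 3 matrix.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return 4x4 matrix.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  T4 <- diag(4)
  T4[1:3, 1:3] <- R
  T4[1:3, 4] <- t
  T4
}

#' @rdname rigid_transform
#' @param T4 4x4 homogeneous transform.
#' @param pts N x 3 point matrix.
#' @export
transform_points <- function(T4, pts) {
  sweep(pts %*% t(T4[1:3, 1:3]), 2, T4[1:3, 4], "+")
}

transform_dirs <- function(T4, dirs) dirs %*% t(T4[1:3, 1:3])

rot_z <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# rotation from axis-angle vector
rot_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_angle <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
}

#' Downsample a surface to a registration point cloud
#'
#' Voxel-grid downsampling (first vertex per cell) with vertex normals.
#'
#' @param surface `textured_surface`.
#' @param voxel voxel pitch (mm).
#' @return list with `points` and `normals` matrices.
#' @export
surface_cloud <- function(surface, voxel = 6) {
  v <- surface$vertices
  n <- vertex_normals(surface)
  key <- paste(floor(v[, 1] / voxel), floor(v[, 2] / voxel),
               floor(v[, 3] / voxel))
  f <- factor(key, levels = unique(key))
  p <- rowsum(v, f, reorder = FALSE) / as.vector(table(f))
  nm <- rowsum(n, f, reorder = FALSE)
  nm <- nm / pmax(sqrt(rowSums(nm^2)), 1e-12)
  dimnames(p) <- NULL; dimnames(nm) <- NULL
  # re-estimate normals at the downsampled scale (local PCA), sign-aligned
  # with the mesh normals: single-vertex normals of a noisy fine mesh are
  # too unstable for point-to-plane residuals
  if (nrow(p) > 30) {
    knn <- cpp_knn_idx(p, 10)
    nm <- cpp_pca_normals(p, knn, nm)
  }
  list(points = p, normals = nm)
}

# interior mask: points whose 8th neighbour lies within ~2 voxel pitches;
# correspondences onto boundary points of a partially overlapping target
# drag the alignment and are excluded
cloud_interior <- function(points, voxel) {
  n <- nrow(points)
  if (n < 20) return(rep(TRUE, n))
  kd <- cpp_knn_dist(points, 8)
  kd[, 8] <= 2.2 * voxel
}

# median shoulder points of a point cloud in the patient frame
shoulder_medians <- function(pts) {
  top <- pts[pts[, 3] > min(pts[, 3]) + 2 / 3 * diff(range(pts[, 3])), ,
             drop = FALSE]
  if (nrow(top) < 10) return(NULL)
  groups <- cut(rank(top[, 1], ties.method = "first"), 5, labels = FALSE)
  if (length(unique(groups)) < 5) return(NULL)
  med <- function(g) apply(top[groups == g, , drop = FALSE], 2, stats::median)
  list(right = med(1), left = med(5))
}

#' Initialize a pairwise registration
#'
#' Estimates the relative z-rotation between two canonicalized views from
#' their median shoulder points, shifts the source so the centres of mass
#' inside the overlapping bounding box align, and derives the
#' correspondence-distance schedule: `lc_max` from normal-compatible
#' forward/backward nearest-neighbour correspondences, `lc_min` from the
#' mean nearest-neighbour spacing, and `sigma_l0` from the spread of the
#' initial correspondence distances.
#'
#' @param target,source clouds from [surface_cloud()] (or
#'   `textured_surface`s, which are downsampled first).
#' @param cfg pipeline configuration (`registration` section).
#' @return list with `T0` (4x4 initial transform source->target), `dphi`
#'   (rad), `lc_max`, `lc_min`, `sigma_l0`; `NULL` when the bounding boxes
#'   do not intersect.
#' @export
init_pair <- function(target, source, cfg = el_config()) {
  rg <- cfg$registration
  if (inherits(target, "textured_surface")) target <- surface_cloud(target, rg$voxel)
  if (inherits(source, "textured_surface")) source <- surface_cloud(source, rg$voxel)
  shT <- shoulder_medians(target$points)
  shS <- shoulder_medians(source$points)
  dphi <- 0
  if (!is.null(shT) && !is.null(shS)) {
    hT <- shT$left - shT$right
    hS <- shS$left - shS$right
    dphi <- atan2(hT[2], hT[1]) - atan2(hS[2], hS[1])
    dphi <- atan2(sin(dphi), cos(dphi))
  }
  R0 <- rot_z(dphi)
  sp <- source$points %*% t(R0)
  lo <- pmax(apply(target$points, 2, min), apply(sp, 2, min))
  hi <- pmin(apply(target$points, 2, max), apply(sp, 2, max))
  if (any(lo >= hi)) return(NULL)
  inbox <- function(p) p[, 1] >= lo[1] & p[, 1] <= hi[1] &
    p[, 2] >= lo[2] & p[, 2] <= hi[2] & p[, 3] >= lo[3] & p[, 3] <= hi[3]
  ti <- inbox(target$points); si <- inbox(sp)
  if (sum(ti) < 10 || sum(si) < 10) return(NULL)
  tb <- target$points[ti, , drop = FALSE]
  sb <- sp[si, , drop = FALSE]
  t_shift <- colMeans(tb) - colMeans(sb)
  T0 <- rigid_transform(R0, t_shift)
  sb2 <- sweep(sb, 2, t_shift, "+")
  tn <- target$normals[ti, , drop = FALSE]
  sn <- (source$normals %*% t(R0))[si, , drop = FALSE]
  # normal-compatible forward/backward correspondences
  fw <- cpp_nn1(tb, sb2)
  bw <- cpp_nn1(sb2, tb)
  cosmin <- if (identical(rg$normal_compat, "dot98")) 0.98 else
    cos(rg$normal_max_angle * pi / 180)
  cf <- rowSums(tn * sn[fw$idx, , drop = FALSE]) >= cosmin
  cb <- rowSums(sn * tn[bw$idx, , drop = FALSE]) >= cosmin
  df <- sqrt(fw$d2[cf]); db <- sqrt(bw$d2[cb])
  if (length(df) < 5 || length(db) < 5) return(NULL)
  lc_max <- max(mean(df) + 2 * stats::sd(df), mean(db) + 2 * stats::sd(db))
  nnt <- cpp_knn_dist(tb, 1); nns <- cpp_knn_dist(sb2, 1)
  lc_min <- mean(c(nnt, nns))
  sigma_l0 <- stats::sd(c(df, db))
  list(T0 = T0, dphi = dphi, lc_max = lc_max, lc_min = lc_min,
       sigma_l0 = sigma_l0)
}

# one unidirectional point-to-plane ICP run at fixed correspondence distance
icp_run <- function(src, tgt, T_init, lc, cfg) {
  rg <- cfg$registration
  T4 <- T_init
  prev <- Inf
  stats_out <- list(lbar = NA_real_, lsd = NA_real_, rmse = NA_real_,
                    n = 0L, rmse_pp = NA_real_)
  iters <- 0L
  tgt_int <- tgt$interior
  if (is.null(tgt_int)) tgt_int <- rep(TRUE, nrow(tgt$points))
  for (it in seq_len(rg$inner_max_iter)) {
    iters <- it
    sp <- transform_points(T4, src$points)
    nn <- cpp_nn1_grid(sp, tgt$points, lc)
    keep <- nn$idx > 0
    keep[keep] <- tgt_int[nn$idx[keep]]
    if (sum(keep) < 10) break
    p <- sp[keep, , drop = FALSE]
    q <- tgt$points[nn$idx[keep], , drop = FALSE]
    n <- tgt$normals[nn$idx[keep], , drop = FALSE]
    r <- rowSums((q - p) * n)
    if (length(r) > 100) {
      lim <- stats::quantile(abs(r), 0.9)
      tk <- abs(r) <= lim
      p <- p[tk, , drop = FALSE]; q <- q[tk, , drop = FALSE]
      n <- n[tk, , drop = FALSE]; r <- r[tk]
    }
    cxn <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
                 p[, 3] * n[, 1] - p[, 1] * n[, 3],
                 p[, 1] * n[, 2] - p[, 2] * n[, 1])
    A <- cbind(cxn, n)
    x <- tryCatch(solve(crossprod(A), crossprod(A, r)),
                  error = function(e) NULL)
    if (is.null(x)) break
    x <- as.vector(x)
    Tu <- rigid_transform(rot_exp(x[1:3]), x[4:6])
    T4 <- Tu %*% T4
    rmse_pp <- sqrt(mean(r^2))
    l <- sqrt(rowSums((q - p)^2))
    stats_out <- list(lbar = mean(l), lsd = stats::sd(l),
                      rmse = sqrt(mean(l^2)), n = sum(keep),
                      rmse_pp = rmse_pp)
    if (is.finite(prev) && abs(prev - rmse_pp) <=
        max(rg$inner_tol * prev, 1e-4)) break
    prev <- rmse_pp
  }
  c(list(T4 = T4, iters = iters), stats_out)
}

# point-to-plane rmse of a candidate transform at correspondence distance lc
pair_error <- function(src, tgt, T4, lc) {
  sp <- transform_points(T4, src$points)
  nn <- cpp_nn1_grid(sp, tgt$points, lc)
  keep <- nn$idx > 0
  if (sum(keep) < 10) return(Inf)
  q <- tgt$points[nn$idx[keep], , drop = FALSE]
  n <- tgt$normals[nn$idx[keep], , drop = FALSE]
  sqrt(mean(rowSums((q - sp[keep, , drop = FALSE]) * n)^2))
}

#' Symmetric point-to-plane registration of a surface pair
#'
#' Repeats forward (source to target) and reverse (target to source,
#' initialized with the forward inverse) point-to-plane ICP runs. After
#' each pair of runs the candidate with lower error *and* lower updated
#' correspondence distance (`l_mean + 2 l_sd` of its correspondences) is
#' accepted and the schedule tightened; when the acceptance test fails, one
#' final run at the minimum correspondence distance is attempted provided
#' the last accepted tightening exceeded the initial distance spread.
#'
#' @param target,source `textured_surface`s or clouds from
#'   [surface_cloud()].
#' @param init result of [init_pair()]; computed when `NULL`.
#' @param cfg pipeline configuration.
#' @return list of class `registration_result`: `T4` (source to target),
#'   `rmse` (mm, point-to-point over final correspondences), `lc_init`,
#'   `lc_final`, `runs`, `converged`.
#' @export
symmetric_icp <- function(target, source, init = NULL, cfg = el_config()) {
  rg <- cfg$registration
  if (inherits(target, "textured_surface")) target <- surface_cloud(target, rg$voxel)
  if (inherits(source, "textured_surface")) source <- surface_cloud(source, rg$voxel)
  if (is.null(init)) init <- init_pair(target, source, cfg)
  if (is.null(init)) return(NULL)
  if (is.null(target$interior))
    target$interior <- cloud_interior(target$points, rg$voxel)
  if (is.null(source$interior))
    source$interior <- cloud_interior(source$points, rg$voxel)
  T_cur <- init$T0
  lc <- max(init$lc_max, rg$l_min)
  lc_init <- lc
  E_cur <- pair_error(source, target, T_cur, lc)
  rmse <- NA_real_
  lc_prev <- Inf
  e_hist <- numeric(0)
  final_done <- FALSE
  runs <- 0L
  repeat {
    if (runs >= rg$max_runs) break
    runs <- runs + 1L
    fw <- icp_run(source, target, T_cur, lc, cfg)
    Ef <- pair_error(source, target, fw$T4, lc)
    lcf <- if (is.finite(fw$lbar)) fw$lbar + 2 * fw$lsd else Inf
    rv <- icp_run(target, source, solve(fw$T4), lc, cfg)
    Tr <- solve(rv$T4)
    Er <- pair_error(source, target, Tr, lc)
    lcr <- if (is.finite(rv$lbar)) rv$lbar + 2 * rv$lsd else Inf
    accept <- NULL
    if (Er < min(E_cur, Ef) && lcr < min(lc, lcf)) {
      accept <- list(T4 = Tr, lc = lcr, E = Er, rmse = rv$rmse)
    } else if (Ef < min(E_cur, Er) && lcf < min(lc, lcr)) {
      accept <- list(T4 = fw$T4, lc = lcf, E = Ef, rmse = fw$rmse)
    } else if (Ef < E_cur && lcf < lc && Ef <= Er) {
      # tie-break when the two directions split the criteria: keep the
      # lower-error candidate as long as it improves on the current state
      accept <- list(T4 = fw$T4, lc = lcf, E = Ef, rmse = fw$rmse)
    } else if (Er < E_cur && lcr < lc) {
      accept <- list(T4 = Tr, lc = lcr, E = Er, rmse = rv$rmse)
    }
    if (is.null(accept)) {
      if (!final_done && lc > rg$l_min &&
          is.finite(lc_prev) && (lc_prev - lc) > init$sigma_l0) {
        final_done <- TRUE
        fw2 <- icp_run(source, target, T_cur, rg$l_min, cfg)
        Ef2 <- pair_error(source, target, fw2$T4, rg$l_min)
        if (Ef2 < pair_error(source, target, T_cur, rg$l_min)) {
          T_cur <- fw2$T4
          lc <- rg$l_min
          rmse <- fw2$rmse
        }
      }
      break
    }
    lc_prev <- lc
    T_cur <- accept$T4
    lc <- accept$lc
    E_cur <- accept$E
    rmse <- accept$rmse
    e_hist <- c(e_hist, accept$E)
    if (length(e_hist) >= 3 &&
        all(diff(utils::tail(e_hist, 3)) > 0)) {
      warning("registration error increasing; returning best so far")
      break
    }
    if (lc <= rg$l_min) break
  }
  if (!is.finite(rmse)) {
    # no accepted run (e.g. the initialization is already optimal):
    # report the correspondence rmse at the current transform
    sp <- transform_points(T_cur, source$points)
    nn <- cpp_nn1_grid(sp, target$points, max(lc, rg$l_min))
    keep <- nn$idx > 0
    if (any(keep)) rmse <- sqrt(mean(nn$d2[keep]))
  }
  structure(list(T4 = T_cur, rmse = rmse, lc_init = lc_init, lc_final = lc,
                 runs = runs, dphi = init$dphi,
                 converged = is.finite(rmse)),
            class = "registration_result")
}

#' Chain pairwise transforms into global view transforms
#'
#' @param pair_results list of `registration_result` for consecutive view
#'   pairs (element i maps view i+1 into view i); `NULL` entries mark
#'   failed pairs, breaking the chain for all downstream views.
#' @return list of 4x4 global transforms (view i into view 1); failed views
#'   carry attribute `aligned = FALSE`.
#' @export
chain_global <- function(pair_results) {
  n <- length(pair_results) + 1
  out <- vector("list", n)
  out[[1]] <- diag(4)
  ok <- TRUE
  for (i in seq_along(pair_results)) {
    pr <- pair_results[[i]]
    if (is.null(pr) || !ok) {
      ok <- FALSE
      out[[i + 1]] <- structure(diag(4), aligned = FALSE)
    } else {
      out[[i + 1]] <- out[[i]] %*% pr$T4
    }
  }
  out
}

#' Register an ordered list of views
#'
#' Runs [init_pair()] and [symmetric_icp()] on each consecutive pair and
#' chains the results.
#'
#' @param surfaces list of canonicalized `textured_surface`s in recording
#'   order.
#' @param cfg pipeline configuration.
#' @return list with `transforms` (global, per view), `pairs`
#'   (`registration_result` list) and `report` (tibble mirroring the
#'   per-pair alignment metrics: iterations, initial/final correspondence
#'   distance, rmse).
#' @export
register_views <- function(surfaces, cfg = el_config()) {
  rg <- cfg$registration
  clouds <- lapply(surfaces, surface_cloud, voxel = rg$voxel)
  pairs <- vector("list", length(surfaces) - 1)
  for (i in seq_len(length(surfaces) - 1)) {
    pairs[[i]] <- symmetric_icp(clouds[[i]], clouds[[i + 1]], cfg = cfg)
  }
  report <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    tibble::tibble(pair = i,
                   runs = if (is.null(p)) NA_integer_ else p$runs,
                   lc_init = if (is.null(p)) NA_real_ else p$lc_init,
                   lc_final = if (is.null(p)) NA_real_ else p$lc_final,
                   rmse = if (is.null(p)) NA_real_ else p$rmse)
  }))
  list(transforms = chain_global(pairs), pairs = pairs, report = report)
}
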