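# Textured surface meshing: depth-image backprojection onto a
# pre-triangulated grid, occlusion and degenerate/skinny triangle removal,
# and placement in the canonical patient frame.

#' Pinhole camera model of the depth/color sensor pair
#'
#' @param depth_intrinsics,color_intrinsics lists with `fx`, `fy`, `cx`,
#'   `cy`, `width`, `height` (pixel units, 1-based pixel centres).
#' @param baseline 3-vector: position of the color sensor in the depth
#'   sensor frame (mm); the lateral offset drives the occlusion test.
#' @return list of class `camera_model`.
#' @export
camera_model <- function(depth_intrinsics, color_intrinsics = depth_intrinsics,
                         baseline = c(25, 0, 0)) {
  structure(list(depth = depth_intrinsics, color = color_intrinsics,
                 baseline = baseline), class = "camera_model")
}

#' Standard intrinsics for a given image size and field of view
#'
#' @param width,height image size in px.
#' @param hfov horizontal field of view, degrees.
#' @return intrinsics list.
#' @export
pinhole_intrinsics <- function(width, height, hfov = 54) {
  f <- (width / 2) / tan(hfov / 2 * pi / 180)
  list(fx = f, fy = f, cx = (width + 1) / 2, cy = (height + 1) / 2,
       width = width, height = height)
}

new_surface <- function(vertices, triangles, uv = NULL, texture = NULL,
                        KW = NA_real_, frame = "camera") {
  structure(list(vertices = vertices, triangles = triangles, uv = uv,
                 texture = texture, KW = KW, frame = frame),
            class = "textured_surface")
}

#' @export
print.textured_surface <- function(x, ...) {
  cat(sprintf("Textured surface: %d vertices, %d triangles (%s frame)\n",
              nrow(x$vertices), nrow(x$triangles), x$frame))
  invisible(x)
}

#' Triangle normals of a surface
#' @param surface `textured_surface`.
#' @return M x 3 matrix of unit triangle normals.
#' @export
triangle_normals <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-12)
}

#' Vertex normals (area-weighted average of incident triangle normals)
#' @param surface `textured_surface`.
#' @return N x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])   # area-weighted
  acc <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    rs <- rowsum(n, tr[, k])
    ids <- as.integer(rownames(rs))
    acc[ids, ] <- acc[ids, ] + rs
  }
  len <- sqrt(rowSums(acc^2))
  acc / pmax(len, 1e-12)
}

# drop triangles by index, then drop unreferenced vertices
remove_triangles <- function(surface, drop_idx) {
  if (length(drop_idx) > 0)
    surface$triangles <- surface$triangles[-drop_idx, , drop = FALSE]
  compact_surface(surface)
}

compact_surface <- function(surface) {
  used <- sort(unique(as.vector(surface$triangles)))
  remap <- integer(nrow(surface$vertices))
  remap[used] <- seq_along(used)
  surface$vertices <- surface$vertices[used, , drop = FALSE]
  if (!is.null(surface$uv)) surface$uv <- surface$uv[used, , drop = FALSE]
  surface$triangles <- matrix(remap[surface$triangles],
                              ncol = 3, dimnames = NULL)
  surface
}

#' Mesh a masked depth frame
#'
#' Backprojects every masked pixel through the depth intrinsics, maps a
#' pre-triangulated grid over the raster (each quad split along the same
#' top-left to bottom-right diagonal, wound so every triangle normal faces
#' the camera), drops triangles touching an undefined or unmasked pixel,
#' and assigns texture coordinates by projecting each vertex into the color
#' sensor.
#'
#' @param frame `depth_frame` (mm).
#' @param mask `seg_mask` or logical matrix; pixels outside are treated as
#'   undefined.
#' @param camera `camera_model`.
#' @param texture optional linear RGB texture to attach.
#' @param KW color temperature the texture was recorded with.
#' @return `textured_surface` in the camera frame (x right, y down,
#'   z viewing direction; mm).
#' @export
depth_to_mesh <- function(frame, mask, camera, texture = NULL, KW = NA_real_) {
  d <- unclass(frame)
  m <- if (inherits(mask, "seg_mask")) mask$mask else mask
  stopifnot(all(dim(m) == dim(d)))
  valid <- m & d > 0
  if (!any(valid)) stop("empty mask: nothing to mesh")
  nr <- nrow(d); nc <- ncol(d)
  di <- camera$depth
  col_px <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row_px <- matrix(rep(seq_len(nr), nc), nr, nc)
  z <- as.vector(d)
  x <- (as.vector(col_px) - di$cx) / di$fx * z
  y <- (as.vector(row_px) - di$cy) / di$fy * z
  verts <- cbind(x, y, z)

  # grid triangles on vertex ids = linear pixel indices (column-major)
  r <- rep(seq_len(nr - 1), nc - 1)
  c0 <- rep(seq_len(nc - 1), each = nr - 1)
  a <- (c0 - 1) * nr + r          # (r, c)
  b <- a + 1L                     # (r+1, c)
  cc <- a + nr + 1L               # (r+1, c+1)
  dd <- a + nr                    # (r, c+1)
  tris <- rbind(cbind(a, b, cc), cbind(a, cc, dd))
  vok <- as.vector(valid)
  keep <- vok[tris[, 1]] & vok[tris[, 2]] & vok[tris[, 3]]
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) stop("mask produced no triangles")

  ci <- camera$color; bl <- camera$baseline
  xc <- verts[, 1] - bl[1]; yc <- verts[, 2] - bl[2]; zc <- verts[, 3] - bl[3]
  u <- ci$fx * xc / pmax(zc, 1e-9) + ci$cx
  v <- ci$fy * yc / pmax(zc, 1e-9) + ci$cy
  s <- new_surface(verts, tris, uv = cbind(u, v), texture = texture, KW = KW)
  compact_surface(s)
}

# signed uv area per triangle; valid camera-facing triangles are negative
# in image coordinates (u right, v down)
uv_signed_area <- function(surface) {
  uv <- surface$uv; tr <- surface$triangles
  ua <- uv[tr[, 1], 1]; va <- uv[tr[, 1], 2]
  ub <- uv[tr[, 2], 1]; vb <- uv[tr[, 2], 2]
  uc <- uv[tr[, 3], 1]; vc <- uv[tr[, 3], 2]
  0.5 * ((ub - ua) * (vc - va) - (uc - ua) * (vb - va))
}

#' Remove occluded triangles
#'
#' A triangle whose winding flips between the depth-image geometry and its
#' uv (color sensor) projection cannot be a real surface patch seen by both
#' sensors: the depth grid guarantees the 3D normal faces the depth camera,
#' so a non-negative uv signed area marks occlusion bridging and the
#' triangle is removed.
#'
#' @param surface `textured_surface` with uv coordinates.
#' @return filtered surface.
#' @export
remove_occluded <- function(surface) {
  stopifnot(!is.null(surface$uv))
  area <- uv_signed_area(surface)
  remove_triangles(surface, which(area >= 0))
}

tri_edge_lengths <- function(v, tr) {
  e <- function(i, j) sqrt(rowSums((v[tr[, i], , drop = FALSE] -
                                    v[tr[, j], , drop = FALSE])^2))
  cbind(e(1, 2), e(2, 3), e(3, 1))
}

tri_angles <- function(len) {
  # angles opposite each edge via the law of cosines; len: M x 3
  ang <- matrix(0, nrow(len), 3)
  for (k in 1:3) {
    a <- len[, k]; b <- len[, k %% 3 + 1]; c <- len[, (k + 1) %% 3 + 1]
    cosv <- pmin(pmax((b^2 + c^2 - a^2) / (2 * b * c), -1), 1)
    ang[, k] <- acos(cosv)
  }
  ang
}

#' Remove degenerate and skinny triangles
#'
#' Removes triangles with a degenerate texture-space footprint (uv area
#' below 0.25 px^2, shortest uv edge below 0.5 px, or extending beyond the
#' texture's top/bottom), then skinny triangles (smallest angle below the
#' configured limit) whose two longest edges are outliers against the edge
#' lengths of the triangles in their local neighbourhood. Removal cascades
#' to adjacent skinny triangles connected through the long edges. Duplicate
#' vertices, unreferenced vertices, and small disconnected patches are
#' cleaned up last.
#'
#' @param surface `textured_surface`.
#' @param cfg pipeline configuration (`meshing` section).
#' @return cleaned surface.
#' @export
remove_degenerate_and_skinny <- function(surface, cfg = el_config()) {
  mc <- cfg$meshing
  drop <- rep(FALSE, nrow(surface$triangles))
  if (!is.null(surface$uv)) {
    area <- abs(uv_signed_area(surface))
    uvlen <- tri_edge_lengths(cbind(surface$uv, 0), surface$triangles)
    vmax_tex <- if (!is.null(surface$texture)) dim(surface$texture)[1] else Inf
    vcoord <- matrix(surface$uv[surface$triangles, 2],
                     ncol = 3)
    drop <- drop | area < mc$min_uv_area |
      pmin(uvlen[, 1], uvlen[, 2], uvlen[, 3]) < mc$min_uv_edge |
      pmin(vcoord[, 1], vcoord[, 2], vcoord[, 3]) < 0.5 |
      pmax(vcoord[, 1], vcoord[, 2], vcoord[, 3]) > vmax_tex + 0.5
  }
  surface <- remove_triangles(surface, which(drop))

  # skinny-triangle pass
  v <- surface$vertices; tr <- surface$triangles
  len <- tri_edge_lengths(v, tr)
  ang <- tri_angles(len)
  min_ang <- pmin(ang[, 1], ang[, 2], ang[, 3]) * 180 / pi
  n_small <- rowSums(ang * 180 / pi < mc$skinny_angle)
  skinny <- which(min_ang < mc$skinny_angle)
  if (length(skinny) > 0) {
    # edge key -> triangles map for adjacency
    nv <- as.numeric(nrow(v))
    edge_key <- function(i, j) as.character(pmin(i, j) * nv + pmax(i, j))
    all_keys <- c(edge_key(tr[, 1], tr[, 2]), edge_key(tr[, 2], tr[, 3]),
                  edge_key(tr[, 3], tr[, 1]))
    tri_of_edge <- split(rep(seq_len(nrow(tr)), 3), all_keys)
    # per-triangle edge order (slots of shortest/middle/longest edge)
    l1 <- len[, 1]; l2 <- len[, 2]; l3 <- len[, 3]
    s_min <- ifelse(l1 <= l2 & l1 <= l3, 1L, ifelse(l2 <= l3, 2L, 3L))
    s_max <- ifelse(l1 >= l2 & l1 >= l3, 1L, ifelse(l2 >= l3, 2L, 3L))
    s_max[s_max == s_min] <- ((s_min[s_max == s_min]) %% 3L) + 1L
    ord <- cbind(s_min, 6L - s_min - s_max, s_max)
    edge_vs <- function(t, e) {          # vertex pair of edge slot e (1=ab..)
      k <- e
      c(tr[t, k], tr[t, k %% 3 + 1])
    }
    to_rm <- rep(FALSE, nrow(tr))
    queue <- c()
    ox <- order(v[, 1])
    vx <- v[ox, 1]
    sp <- split(rep(seq_len(nrow(tr)), 3), as.vector(tr))
    vt_map <- vector("list", nrow(v))
    vt_map[as.integer(names(sp))] <- sp
    for (t in skinny) {
      ea_slot <- ord[t, 1]; eb_slot <- ord[t, 2]; ec_slot <- ord[t, 3]
      la <- len[t, ea_slot]; lb <- len[t, eb_slot]; lc <- len[t, ec_slot]
      # tip vertex: common vertex of the two longest edges
      vb <- edge_vs(t, eb_slot); vc <- edge_vs(t, ec_slot)
      tip <- intersect(vb, vc)[1]
      amid <- colMeans(v[edge_vs(t, ea_slot), , drop = FALSE])
      rad <- max(0.9 * lb, la)
      ctrs <- rbind(v[tip, ], amid)
      # prefilter vertices by x range before the radius test
      xr <- range(ctrs[, 1]) + c(-rad, rad)
      lo <- findInterval(xr[1], vx) + 1L
      hi <- findInterval(xr[2], vx)
      if (hi < lo) next
      cand_v <- ox[lo:hi]
      vv <- v[cand_v, , drop = FALSE]
      d2a <- (vv[, 1] - ctrs[1, 1])^2 + (vv[, 2] - ctrs[1, 2])^2 +
             (vv[, 3] - ctrs[1, 3])^2
      d2b <- (vv[, 1] - ctrs[2, 1])^2 + (vv[, 2] - ctrs[2, 2])^2 +
             (vv[, 3] - ctrs[2, 3])^2
      close_id <- cand_v[d2a <= rad^2 | d2b <= rad^2]
      close_v <- logical(nrow(v))
      close_v[close_id] <- TRUE
      cand_t <- unique(unlist(vt_map[close_id], use.names = FALSE))
      nb <- cand_t[close_v[tr[cand_t, 1]] & close_v[tr[cand_t, 2]] &
                   close_v[tr[cand_t, 3]]]
      nb <- setdiff(nb, t)
      if (length(nb) < 1) next
      e_all <- as.vector(len[nb, ])
      m <- mean(e_all); s <- if (length(e_all) > 1) stats::sd(e_all) else 0
      lim <- m + mc$skinny_sigma_factor * s
      if (lc > lim && lb > lim) {
        to_rm[t] <- TRUE
        queue <- c(queue, t)
      } else if (lc > lim && n_small[t] == 2) {
        ec_tris <- tri_of_edge[[edge_key(vc[1], vc[2])]]
        nb_ec <- setdiff(ec_tris, t)
        nb_ec <- nb_ec[min_ang[nb_ec] < mc$skinny_angle]
        to_rm[nb_ec] <- TRUE
      }
    }
    # cascade: skinny neighbours over eb/ec edges of removed triangles
    while (length(queue) > 0) {
      t <- queue[1]; queue <- queue[-1]
      for (slot in ord[t, 2:3]) {
        vs <- edge_vs(t, slot)
        nbs <- setdiff(tri_of_edge[[edge_key(vs[1], vs[2])]], t)
        nbs <- nbs[min_ang[nbs] < mc$skinny_angle & !to_rm[nbs]]
        if (length(nbs) > 0) {
          to_rm[nbs] <- TRUE
          queue <- c(queue, nbs)
        }
      }
    }
    surface <- remove_triangles(surface, which(to_rm))
  }

  surface <- merge_duplicate_vertices(surface)
  surface <- remove_small_patches(surface, mc$min_patch_triangles)
  surface
}

merge_duplicate_vertices <- function(surface) {
  key <- paste(surface$vertices[, 1], surface$vertices[, 2],
               surface$vertices[, 3])
  first <- match(key, key)
  if (all(first == seq_along(first))) return(surface)
  surface$triangles <- matrix(first[surface$triangles], ncol = 3)
  # drop triangles that collapsed
  degen <- surface$triangles[, 1] == surface$triangles[, 2] |
           surface$triangles[, 2] == surface$triangles[, 3] |
           surface$triangles[, 1] == surface$triangles[, 3]
  surface$triangles <- surface$triangles[!degen, , drop = FALSE]
  compact_surface(surface)
}

remove_small_patches <- function(surface, min_triangles) {
  tr <- surface$triangles
  n <- nrow(surface$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(tr))) {
    a <- find(tr[k, 1]); b <- find(tr[k, 2]); c <- find(tr[k, 3])
    parent[b] <- a; parent[c] <- a
  }
  comp <- vapply(tr[, 1], find, integer(1))
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes >= min_triangles])
  if (length(big) == length(sizes)) return(surface)
  keep <- comp %in% big
  surface$triangles <- tr[keep, , drop = FALSE]
  compact_surface(surface)
}

#' Place a surface in the canonical patient frame
#'
#' Permutes the camera axes so +z points toward the patient's head and +x
#' from the patient's right to left, and shifts the origin along the
#' camera's central viewing axis: the depth coordinate of the origin is the
#' mean of the median depths of the outer two of five lateral subgroups
#' within the top third of the torso (the shoulder medians). A surface
#' whose longest extent is already along z is assumed canonical and only
#' re-centred.
#'
#' @param surface `textured_surface` in the camera frame.
#' @return canonicalized surface with attribute `shoulders` (right/left
#'   median points used for registration initialization).
#' @export
canonicalize <- function(surface) {
  v <- surface$vertices
  ext <- apply(v, 2, function(x) diff(range(x)))
  if (!(ext[3] >= ext[2])) {
    # camera frame: x right, y down, z forward -> x left, y posterior, z up
    v <- cbind(v[, 1], v[, 3], -v[, 2])
  }
  top <- v[, 3] > min(v[, 3]) + 2 / 3 * diff(range(v[, 3]))
  top_pts <- v[top, , drop = FALSE]
  groups <- cut(rank(top_pts[, 1], ties.method = "first"), 5, labels = FALSE)
  if (length(unique(groups)) < 5) {
    warning("fewer than 5 lateral subgroups; falling back to bounding-box centre")
    y0 <- mean(range(v[, 2]))
    shoulders <- NULL
  } else {
    med_pt <- function(g) apply(top_pts[groups == g, , drop = FALSE], 2,
                                stats::median)
    vr <- med_pt(1); vl <- med_pt(5)
    y0 <- (vr[2] + vl[2]) / 2
    shoulders <- list(right = vr - c(0, y0, 0), left = vl - c(0, y0, 0))
  }
  v[, 2] <- v[, 2] - y0
  surface$vertices <- v
  surface$frame <- "patient"
  attr(surface, "shoulders") <- shoulders
  attr(surface, "origin_shift") <- y0
  surface
}
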