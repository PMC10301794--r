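# Foreground/background segmentation of 16-bit depth images: table-driven
# gradient-weighted Gaussian smoothing, octagonal-Laplacian zero-crossing
# edges with Canny-style primary/minor limits, connected-component patient
# selection, and a per-row depth-band outlier filter.

#' Depth frame constructor
#'
#' @param d integer matrix of depths in mm; 0 encodes "no valid depth".
#' @param intrinsics optional pinhole intrinsics list (`fx`, `fy`, `cx`,
#'   `cy`).
#' @return matrix of class `depth_frame`.
#' @export
depth_frame <- function(d, intrinsics = NULL) {
  stopifnot(is.matrix(d), all(d >= 0))
  structure(round(d), class = "depth_frame", intrinsics = intrinsics)
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# integer-quantized gradient magnitude weights: distinct weights for the
# rounded gradient levels, fetched by left bisection over squared midpoint
# boundaries so no square root is taken per pixel
grad_weight_table <- function(sigma, max_level = NULL) {
  if (is.null(max_level)) max_level <- ceiling(6 * sigma)
  levels <- 0:max_level
  list(levels = levels,
       boundaries_sq = (levels[-1] - 0.5)^2,
       w = exp(-levels^2 / (2 * sigma^2)))
}

# squared gradient magnitude from half-pixel central differences; undefined
# neighbours fall back to the centre value
grad_sq <- function(d) {
  def <- d > 0
  pick <- function(dr, dc) {
    s <- shift_mat(d, dr, dc); sd <- shift_mat(def, dr, dc, FALSE)
    ifelse(sd, s, d)
  }
  gx <- (pick(0, -1) - pick(0, 1)) / 2
  gy <- (pick(-1, 0) - pick(1, 0)) / 2
  gx^2 + gy^2
}

#' Smooth a depth image
#'
#' Gaussian smoothing whose neighbour weights are attenuated by each
#' neighbour's depth-gradient magnitude (edge-preserving). Gradient
#' magnitudes are rounded to integers and their weights fetched from a
#' precomputed table via a left-bisection search over squared boundary
#' values. Undefined pixels (depth 0) are copied unchanged and never
#' contribute to their neighbours.
#'
#' @param frame `depth_frame`.
#' @param cfg pipeline configuration (`segmentation` section).
#' @param exact use exact exponentials instead of the lookup table (the
#'   reference path used in validation).
#' @return smoothed `depth_frame` (values rounded to mm).
#' @export
smooth_depth <- function(frame, cfg = el_config(), exact = FALSE) {
  s <- cfg$segmentation
  d <- unclass(frame)
  def <- d > 0
  g2 <- grad_sq(d)
  if (exact) {
    wg <- exp(-g2 / (2 * s$grad_sigma^2))
  } else {
    tab <- grad_weight_table(s$grad_sigma)
    idx <- findInterval(g2, tab$boundaries_sq)     # 0-based level
    wg <- matrix(tab$w[pmin(idx, length(tab$w) - 1L) + 1L], nrow(d), ncol(d))
  }
  half <- 2L
  offs <- expand.grid(dr = -half:half, dc = -half:half)
  num <- matrix(0, nrow(d), ncol(d))
  den <- matrix(0, nrow(d), ncol(d))
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    ws <- exp(-(dr^2 + dc^2) / (2 * cfg$segmentation$smooth_sigma^2))
    dj <- shift_mat(d, dr, dc)
    defj <- shift_mat(def, dr, dc, FALSE)
    wgj <- shift_mat(wg, dr, dc)
    w <- ws * wgj * defj
    num <- num + w * dj
    den <- den + w
  }
  sm <- ifelse(den > 0, num / den, d)
  sm[!def] <- 0
  depth_frame(round(sm), attr(frame, "intrinsics"))
}

# octagonal Laplacian: corner weights scaled by 1/sqrt(2) so all eight
# neighbour distances are effectively equal; undefined neighbours take the
# centre value
octagonal_laplacian <- function(d) {
  def <- d > 0
  acc <- matrix(0, nrow(d), ncol(d))
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (o in offs) {
    s <- shift_mat(d, o[1], o[2]); sd <- shift_mat(def, o[1], o[2], FALSE)
    acc <- acc + (ifelse(sd, s, d) - d)
  }
  for (o in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    s <- shift_mat(d, o[1], o[2]); sd <- shift_mat(def, o[1], o[2], FALSE)
    acc <- acc + (ifelse(sd, s, d) - d) / sqrt(2)
  }
  acc[!def] <- 0
  -acc   # center-positive convention
}

#' Detect depth edges
#'
#' Candidate edges are zero crossings of the octagonal Laplacian (sign
#' change between opposing 8-neighbours). The depth step of each candidate
#' is the maximum over the four opposing neighbour pairs: the two-sided
#' difference where both neighbours are defined, or the doubled one-sided
#' difference to the centre otherwise. Steps above the primary limit make
#' primary edges; the remaining candidates are kept as minor edges when the
#' modified Canny rule holds.
#'
#' @param dsm smoothed `depth_frame`.
#' @param cfg pipeline configuration.
#' @return list with logical matrices `edges`, `primary`, `minor` and the
#'   step magnitude matrix `step`.
#' @export
detect_edges <- function(dsm, cfg = el_config()) {
  s <- cfg$segmentation
  d <- unclass(dsm)
  def <- d > 0
  L <- octagonal_laplacian(d)
  pairs <- list(list(c(0, -1), c(0, 1)), list(c(-1, 0), c(1, 0)),
                list(c(-1, -1), c(1, 1)), list(c(-1, 1), c(1, -1)))
  cand <- matrix(FALSE, nrow(d), ncol(d))
  step <- matrix(0, nrow(d), ncol(d))
  for (p in pairs) {
    La <- shift_mat(L, p[[1]][1], p[[1]][2])
    Lb <- shift_mat(L, p[[2]][1], p[[2]][2])
    cand <- cand | (La * Lb < 0)
    Da <- shift_mat(d, p[[1]][1], p[[1]][2])
    Db <- shift_mat(d, p[[2]][1], p[[2]][2])
    da <- Da > 0; db <- Db > 0
    sv <- ifelse(da & db, abs(Da - Db),
          ifelse(da, 2 * abs(Da - d),
          ifelse(db, 2 * abs(Db - d), 0)))
    step <- pmax(step, sv)
  }
  cand <- cand & def
  primary <- cand & step > s$edge_primary
  minor_rule <- (step > s$edge_minor) &
    ((step > s$edge_primary) |
       ((step - s$edge_minor) / pmax(s$edge_primary - step, 1e-12) > 1))
  minor <- cand & !primary & minor_rule
  list(edges = primary | minor, primary = primary, minor = minor, step = step)
}

#' Select the patient foreground
#'
#' Builds the binary patient mask: defined-depth, non-edge pixels are
#' labelled within the central segment of a 3x3 split; the largest
#' 4-connected component touching the segment boundary is extended over the
#' full image by flood fill from its centre of mass; adjacent edge pixels
#' join the depth-band statistics; finally a per-row depth band rejects
#' background pixels. Components smaller than the minimum size (or with an
#' invalid band) are skipped and the next-largest tried.
#'
#' @param frame original `depth_frame` (band statistics use raw depths).
#' @param edges edge detection result from [detect_edges()].
#' @param cfg pipeline configuration.
#' @return object of class `seg_mask` (fields `mask`, `edges`, `primary`,
#'   `minor`, `band`), or `NULL` when no component qualifies.
#' @export
select_patient <- function(frame, edges, cfg = el_config()) {
  s <- cfg$segmentation
  d <- unclass(frame)
  valid <- d > 0 & !edges$edges
  nr <- nrow(d); nc <- ncol(d)
  r0 <- floor(nr / 3) + 1L; r1 <- floor(2 * nr / 3)
  c0 <- floor(nc / 3) + 1L; c1 <- floor(2 * nc / 3)
  central <- valid[r0:r1, c0:c1]
  lab <- cpp_label4(central)
  if (max(lab) == 0) return(NULL)
  sizes <- tabulate(lab[lab > 0])
  touches <- vapply(seq_along(sizes), function(k) {
    any(lab[1, ] == k) || any(lab[nrow(lab), ] == k) ||
      any(lab[, 1] == k) || any(lab[, ncol(lab)] == k)
  }, logical(1))
  cand <- which(touches)
  if (length(cand) == 0) return(NULL)
  # largest first; ties broken by centroid closest to the image centre
  cent_d <- vapply(cand, function(k) {
    ij <- which(lab == k, arr.ind = TRUE)
    sqrt((mean(ij[, 1]) + r0 - 1 - (nr + 1) / 2)^2 +
         (mean(ij[, 2]) + c0 - 1 - (nc + 1) / 2)^2)
  }, numeric(1))
  cand <- cand[order(-sizes[cand], cent_d)]

  for (k in cand) {
    ij <- which(lab == k, arr.ind = TRUE)
    com <- round(colMeans(ij))
    seed_r <- com[1] + r0 - 1L; seed_c <- com[2] + c0 - 1L
    if (!valid[seed_r, seed_c]) {
      # centre of mass may fall off the component; use its nearest member
      dd <- (ij[, 1] - com[1])^2 + (ij[, 2] - com[2])^2
      seed_r <- ij[which.min(dd), 1] + r0 - 1L
      seed_c <- ij[which.min(dd), 2] + c0 - 1L
    }
    l4p <- cpp_floodfill4(valid, seed_r, seed_c)
    # adjacent edge pixels join the band statistics
    ring <- (shift_mat(l4p, 1, 0, FALSE) | shift_mat(l4p, -1, 0, FALSE) |
             shift_mat(l4p, 0, 1, FALSE) | shift_mat(l4p, 0, -1, FALSE)) &
            edges$edges & d > 0
    stat_px <- l4p | ring
    rows_close <- suppressWarnings(apply(ifelse(stat_px & d > 0, d, NA), 1,
                                         min, na.rm = TRUE))
    rows_far <- suppressWarnings(apply(ifelse(stat_px & d > 0, d, NA), 1,
                                       max, na.rm = TRUE))
    keep <- is.finite(rows_close)
    rc <- rows_close[keep]; rf <- rows_far[keep]
    if (length(rc) == 0) next
    band <- depth_band(rc, rf, s$d_near)
    d_close <- band[1]; d_far <- band[2]
    if (!is.finite(d_far) || !is.finite(d_close) || d_close > d_far) next
    mask <- l4p & d >= d_close & d <= d_far
    if (sum(mask) < s$min_component) next
    return(structure(list(mask = mask, edges = edges$edges,
                          primary = edges$primary, minor = edges$minor,
                          band = c(close = d_close, far = d_far)),
                     class = "seg_mask"))
  }
  NULL
}

# per-row depth band: D_far from the row maxima, D_close from the row
# minima (clamped by the closest valid sensor distance). The comparisons in
# the caller are inclusive so that perfectly flat foregrounds survive.
depth_band <- function(rows_close, rows_far, d_near) {
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  d_far <- min(max(rows_far) + (max(rows_far) - min(rows_close)) / 3,
               mean(rows_far) + 3 * sd0(rows_far))
  d_close <- max(min(rows_close) -
                   (max(rows_close) - min(rows_close)) / 3,
                 mean(rows_close) - 3 * sd0(rows_far), d_near)
  c(close = d_close, far = d_far)
}

#' Full depth segmentation of one frame
#'
#' Convenience wrapper chaining [smooth_depth()], [detect_edges()] and
#' [select_patient()].
#'
#' @param frame `depth_frame`.
#' @param cfg pipeline configuration.
#' @return `seg_mask` or `NULL`.
#' @export
segment_depth <- function(frame, cfg = el_config()) {
  dsm <- smooth_depth(frame, cfg)
  ed <- detect_edges(dsm, cfg)
  select_patient(frame, ed, cfg)
}
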