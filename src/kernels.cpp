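#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdlib>
#include <limits>
#include <unordered_map>
using namespace Rcpp;

// Nearest neighbour of each query point among the reference points.
// Returns 1-based index and squared distance. Brute force; the point sets
// handled here (downsampled surfaces, marker clouds) stay small enough that
// this beats tree construction overheads.
// [[Rcpp::export]]
List cpp_nn1(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) { rx[j] = ref(j,0); ry[j] = ref(j,1); rz[j] = ref(j,2); }
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    double best = std::numeric_limits<double>::infinity();
    int bj = -1;
    for (int j = 0; j < nr; ++j) {
      double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      double d = dx*dx + dy*dy + dz*dz;
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1;
    d2[i] = best;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

// Radius-bounded nearest neighbour via a uniform voxel hash (cell size =
// max_dist). idx = 0 when no reference point lies within max_dist.
// [[Rcpp::export]]
List cpp_nn1_grid(NumericMatrix query, NumericMatrix ref, double max_dist) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq, R_PosInf);
  if (nr == 0 || max_dist <= 0) return List::create(_["idx"] = idx, _["d2"] = d2);
  const double cs = max_dist;
  double ox = R_PosInf, oy = R_PosInf, oz = R_PosInf;
  for (int j = 0; j < nr; ++j) {
    ox = std::min(ox, ref(j,0)); oy = std::min(oy, ref(j,1));
    oz = std::min(oz, ref(j,2));
  }
  auto cellof = [&](double x, double o) {
    return (long long)std::floor((x - o) / cs);
  };
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(nr * 2);
  auto key = [](long long cx, long long cy, long long cz) {
    return ((cx * 73856093LL) ^ (cy * 19349663LL) ^ (cz * 83492791LL));
  };
  std::vector<long long> kx(nr), ky(nr), kz(nr);
  for (int j = 0; j < nr; ++j) {
    kx[j] = cellof(ref(j,0), ox); ky[j] = cellof(ref(j,1), oy);
    kz[j] = cellof(ref(j,2), oz);
    grid[key(kx[j], ky[j], kz[j])].push_back(j);
  }
  const double md2 = max_dist * max_dist;
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    long long cx = cellof(qx, ox), cy = cellof(qy, oy), cz = cellof(qz, oz);
    double best = md2;
    int bj = -1;
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(key(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          const std::vector<int>& cell = it->second;
          for (size_t m = 0; m < cell.size(); ++m) {
            int j = cell[m];
            // guard against hash collisions mapping distant cells together
            if (std::llabs(kx[j] - cx) > 1 || std::llabs(ky[j] - cy) > 1 ||
                std::llabs(kz[j] - cz) > 1) continue;
            double ddx = qx - ref(j,0), ddy = qy - ref(j,1), ddz = qz - ref(j,2);
            double d = ddx*ddx + ddy*ddy + ddz*ddz;
            if (d <= best) { best = d; bj = j; }
          }
        }
    if (bj >= 0) { idx[i] = bj + 1; d2[i] = best; }
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

// Distances to the k nearest neighbours (excluding self) of each point.
// Returns an n x k matrix of distances, ascending per row.
// [[Rcpp::export]]
NumericMatrix cpp_knn_dist(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k >= n) k = n - 1;
  NumericMatrix out(n, k);
  std::vector<double> px(n), py(n), pz(n);
  for (int j = 0; j < n; ++j) { px[j] = pts(j,0); py[j] = pts(j,1); pz[j] = pts(j,2); }
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
      d[j] = dx*dx + dy*dy + dz*dz;
    }
    d[i] = std::numeric_limits<double>::infinity();
    std::vector<double> dc(d);
    std::partial_sort(dc.begin(), dc.begin() + k, dc.end());
    for (int m = 0; m < k; ++m) out(i, m) = std::sqrt(dc[m]);
  }
  return out;
}

// Indices of the k nearest neighbours (excluding self), n x k, 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_idx(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k >= n) k = n - 1;
  IntegerMatrix out(n, k);
  std::vector<double> px(n), py(n), pz(n);
  for (int j = 0; j < n; ++j) { px[j] = pts(j,0); py[j] = pts(j,1); pz[j] = pts(j,2); }
  std::vector< std::pair<double,int> > d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
      d[j] = std::make_pair(dx*dx + dy*dy + dz*dz, j);
    }
    d[i].first = std::numeric_limits<double>::infinity();
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int m = 0; m < k; ++m) out(i, m) = d[m].second + 1;
    for (int j = 0; j < n; ++j) d[j].second = j;
  }
  return out;
}

// Local PCA normals: smallest-eigenvector of the covariance of each
// point's k neighbours (self included), sign-aligned with `orient`.
// [[Rcpp::export]]
NumericMatrix cpp_pca_normals(NumericMatrix pts, IntegerMatrix knn,
                              NumericMatrix orient) {
  const int n = pts.nrow(), k = knn.ncol();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double mx = pts(i,0), my = pts(i,1), mz = pts(i,2);
    for (int m = 0; m < k; ++m) {
      int j = knn(i,m) - 1;
      mx += pts(j,0); my += pts(j,1); mz += pts(j,2);
    }
    mx /= (k + 1); my /= (k + 1); mz /= (k + 1);
    double c00=0,c01=0,c02=0,c11=0,c12=0,c22=0;
    for (int m = -1; m < k; ++m) {
      int j = (m < 0) ? i : knn(i,m) - 1;
      double dx = pts(j,0)-mx, dy = pts(j,1)-my, dz = pts(j,2)-mz;
      c00+=dx*dx; c01+=dx*dy; c02+=dx*dz; c11+=dy*dy; c12+=dy*dz; c22+=dz*dz;
    }
    // smallest eigenvector of symmetric 3x3 by inverse power iteration
    // via cross products of two largest-variance directions: use the
    // robust closed form through eigen decomposition (Jacobi, 15 sweeps)
    double A[3][3] = {{c00,c01,c02},{c01,c11,c12},{c02,c12,c22}};
    double V[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int sweep = 0; sweep < 15; ++sweep) {
      for (int p = 0; p < 2; ++p) for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(A[p][q]) < 1e-18) continue;
        double theta = 0.5 * std::atan2(2 * A[p][q], A[q][q] - A[p][p]);
        double c = std::cos(theta), s = std::sin(theta);
        for (int r = 0; r < 3; ++r) {
          double arp = A[r][p], arq = A[r][q];
          A[r][p] = c*arp - s*arq; A[r][q] = s*arp + c*arq;
        }
        for (int r = 0; r < 3; ++r) {
          double apr = A[p][r], aqr = A[q][r];
          A[p][r] = c*apr - s*aqr; A[q][r] = s*apr + c*aqr;
        }
        for (int r = 0; r < 3; ++r) {
          double vrp = V[r][p], vrq = V[r][q];
          V[r][p] = c*vrp - s*vrq; V[r][q] = s*vrp + c*vrq;
        }
      }
    }
    int mi = 0;
    if (A[1][1] < A[mi][mi]) mi = 1;
    if (A[2][2] < A[mi][mi]) mi = 2;
    double nx = V[0][mi], ny = V[1][mi], nz = V[2][mi];
    double len = std::sqrt(nx*nx + ny*ny + nz*nz);
    if (len < 1e-12) { nx = 0; ny = 0; nz = 1; len = 1; }
    nx /= len; ny /= len; nz /= len;
    double dot = nx*orient(i,0) + ny*orient(i,1) + nz*orient(i,2);
    if (dot < 0) { nx = -nx; ny = -ny; nz = -nz; }
    out(i,0) = nx; out(i,1) = ny; out(i,2) = nz;
  }
  return out;
}

// For each query point: does at least one reference point lie within radius?
// [[Rcpp::export]]
LogicalVector cpp_has_neighbor_within(NumericMatrix query, NumericMatrix ref,
                                      double radius) {
  const int nq = query.nrow(), nr = ref.nrow();
  const double r2 = radius * radius;
  LogicalVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    bool found = false;
    for (int j = 0; j < nr && !found; ++j) {
      double dx = qx - ref(j,0), dy = qy - ref(j,1), dz = qz - ref(j,2);
      if (dx*dx + dy*dy + dz*dz <= r2) found = true;
    }
    out[i] = found;
  }
  return out;
}

// 4-connected component labelling of a logical matrix. 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> qr, qc;
  for (int c0 = 0; c0 < nc; ++c0) for (int r0 = 0; r0 < nr; ++r0) {
    if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
    ++next;
    qr.clear(); qc.clear();
    qr.push_back(r0); qc.push_back(c0);
    lab(r0, c0) = next;
    while (!qr.empty()) {
      int r = qr.back(), c = qc.back();
      qr.pop_back(); qc.pop_back();
      const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int m = 0; m < 4; ++m) {
        int rr = r + dr[m], cc = c + dc[m];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (mask(rr, cc) && lab(rr, cc) == 0) {
          lab(rr, cc) = next;
          qr.push_back(rr); qc.push_back(cc);
        }
      }
    }
  }
  return lab;
}

// 4-connected flood fill over `open` starting from (seed_r, seed_c), 1-based.
// [[Rcpp::export]]
LogicalMatrix cpp_floodfill4(LogicalMatrix open, int seed_r, int seed_c) {
  const int nr = open.nrow(), nc = open.ncol();
  LogicalMatrix vis(nr, nc);
  int r0 = seed_r - 1, c0 = seed_c - 1;
  if (r0 < 0 || r0 >= nr || c0 < 0 || c0 >= nc || !open(r0, c0)) return vis;
  std::vector<int> qr, qc;
  qr.push_back(r0); qc.push_back(c0);
  vis(r0, c0) = true;
  while (!qr.empty()) {
    int r = qr.back(), c = qc.back();
    qr.pop_back(); qc.pop_back();
    const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
    for (int m = 0; m < 4; ++m) {
      int rr = r + dr[m], cc = c + dc[m];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (open(rr, cc) && !vis(rr, cc)) {
        vis(rr, cc) = true;
        qr.push_back(rr); qc.push_back(cc);
      }
    }
  }
  return vis;
}

// Minimum spanning tree of the mutual-reachability graph (Prim, O(n^2)).
// core: per-point core distance. Returns edges (from, to, weight) with
// 1-based indices, in the order Prim adds them.
// [[Rcpp::export]]
DataFrame cpp_mreach_mst(NumericMatrix pts, NumericVector core) {
  const int n = pts.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int j = 0; j < n; ++j) { px[j] = pts(j,0); py[j] = pts(j,1); pz[j] = pts(j,2); }
  std::vector<bool> in(n, false);
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  std::vector<int> from(n, -1);
  IntegerVector ef(n - 1), et(n - 1);
  NumericVector ew(n - 1);
  int cur = 0;
  in[0] = true;
  for (int step = 0; step < n - 1; ++step) {
    // relax edges from `cur`
    for (int j = 0; j < n; ++j) {
      if (in[j]) continue;
      double dx = px[cur]-px[j], dy = py[cur]-py[j], dz = pz[cur]-pz[j];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      double w = std::max(d, std::max(core[cur], core[j]));
      if (w < best[j]) { best[j] = w; from[j] = cur; }
    }
    double mn = std::numeric_limits<double>::infinity();
    int nxt = -1;
    for (int j = 0; j < n; ++j)
      if (!in[j] && best[j] < mn) { mn = best[j]; nxt = j; }
    ef[step] = from[nxt] + 1;
    et[step] = nxt + 1;
    ew[step] = best[nxt];
    in[nxt] = true;
    cur = nxt;
  }
  return DataFrame::create(_["from"] = ef, _["to"] = et, _["weight"] = ew);
}

// Locate query points inside uv triangles. tri_u/tri_v: ntri x 3 matrices of
// the triangle corner uv coordinates. Uses a uniform bin grid over the uv
// bounding box. Returns 1-based triangle index (0 = not inside any) and
// barycentric coordinates.
// [[Rcpp::export]]
List cpp_locate_uv(NumericVector qu, NumericVector qv,
                   NumericMatrix tri_u, NumericMatrix tri_v) {
  const int nq = qu.size(), nt = tri_u.nrow();
  IntegerVector tri(nq);
  NumericMatrix bary(nq, 3);
  if (nt == 0) return List::create(_["tri"] = tri, _["bary"] = bary);
  double umin = R_PosInf, umax = R_NegInf, vmin = R_PosInf, vmax = R_NegInf;
  for (int t = 0; t < nt; ++t) for (int k = 0; k < 3; ++k) {
    umin = std::min(umin, tri_u(t,k)); umax = std::max(umax, tri_u(t,k));
    vmin = std::min(vmin, tri_v(t,k)); vmax = std::max(vmax, tri_v(t,k));
  }
  int nbu = std::max(1, (int)std::floor(std::sqrt((double)nt / 2.0)));
  int nbv = nbu;
  double du = (umax - umin) / nbu + 1e-12, dv = (vmax - vmin) / nbv + 1e-12;
  std::vector< std::vector<int> > bins(nbu * nbv);
  for (int t = 0; t < nt; ++t) {
    double tu0 = std::min({tri_u(t,0), tri_u(t,1), tri_u(t,2)});
    double tu1 = std::max({tri_u(t,0), tri_u(t,1), tri_u(t,2)});
    double tv0 = std::min({tri_v(t,0), tri_v(t,1), tri_v(t,2)});
    double tv1 = std::max({tri_v(t,0), tri_v(t,1), tri_v(t,2)});
    int bu0 = std::max(0, std::min(nbu - 1, (int)((tu0 - umin) / du)));
    int bu1 = std::max(0, std::min(nbu - 1, (int)((tu1 - umin) / du)));
    int bv0 = std::max(0, std::min(nbv - 1, (int)((tv0 - vmin) / dv)));
    int bv1 = std::max(0, std::min(nbv - 1, (int)((tv1 - vmin) / dv)));
    for (int bu = bu0; bu <= bu1; ++bu)
      for (int bv = bv0; bv <= bv1; ++bv)
        bins[bu * nbv + bv].push_back(t);
  }
  const double eps = 1e-9;
  for (int i = 0; i < nq; ++i) {
    double u = qu[i], v = qv[i];
    if (u < umin || u > umax || v < vmin || v > vmax) { tri[i] = 0; continue; }
    int bu = std::max(0, std::min(nbu - 1, (int)((u - umin) / du)));
    int bv = std::max(0, std::min(nbv - 1, (int)((v - vmin) / dv)));
    const std::vector<int>& cand = bins[bu * nbv + bv];
    tri[i] = 0;
    for (size_t m = 0; m < cand.size(); ++m) {
      int t = cand[m];
      double x1 = tri_u(t,0), y1 = tri_v(t,0);
      double x2 = tri_u(t,1), y2 = tri_v(t,1);
      double x3 = tri_u(t,2), y3 = tri_v(t,2);
      double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
      if (std::fabs(det) < 1e-14) continue;
      double l1 = ((y2 - y3) * (u - x3) + (x3 - x2) * (v - y3)) / det;
      double l2 = ((y3 - y1) * (u - x3) + (x1 - x3) * (v - y3)) / det;
      double l3 = 1.0 - l1 - l2;
      if (l1 >= -eps && l2 >= -eps && l3 >= -eps) {
        tri[i] = t + 1;
        bary(i,0) = l1; bary(i,1) = l2; bary(i,2) = l3;
        break;
      }
    }
  }
  return List::create(_["tri"] = tri, _["bary"] = bary);
}
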