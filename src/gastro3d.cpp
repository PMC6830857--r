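// Compiled geometry kernels: brute-force / cell-grid neighbor searches,
// local RANSAC plane fitting, PCA normals, signed-distance-field evaluation,
// marching-tetrahedra polygonization, point-to-mesh distance and ray casting.
// All routines are single-threaded and deterministic (ties broken by index,
// RNG is std::mt19937_64 with caller-supplied seeds).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <map>
#include <random>
#include <vector>

using namespace Rcpp;

static inline double sq(double x) { return x * x; }

static inline double dist2_rows(const NumericMatrix &a, int i,
                                const NumericMatrix &b, int j) {
  return sq(a(i, 0) - b(j, 0)) + sq(a(i, 1) - b(j, 1)) + sq(a(i, 2) - b(j, 2));
}

// ---------------------------------------------------------------------------
// nearest-neighbour distance of every point (self excluded), O(N^2)
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d2 = dist2_rows(pts, i, pts, j);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// for each row of a, the minimum distance to any row of b
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double d2 = dist2_rows(a, i, b, j);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// count of neighbours within `radius` (inclusive), self excluded
// [[Rcpp::export]]
IntegerVector cpp_radius_counts(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  const double r2 = radius * radius;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dist2_rows(pts, i, pts, j) <= r2) ++c;
    }
    out[i] = c;
  }
  return out;
}

struct Cand {
  double d2;
  int idx;
};
static inline bool cand_less(const Cand &a, const Cand &b) {
  if (a.d2 != b.d2) return a.d2 < b.d2;
  return a.idx < b.idx;  // deterministic tie-break: lowest index
}

// k nearest neighbours of every point among `pts` (self excluded).
// Returns 1-based index matrix and distance matrix, columns ordered by
// (distance, index).
// [[Rcpp::export]]
List cpp_knn_self(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k > n - 1) k = n - 1;
  if (k < 0) k = 0;
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<Cand> cand(n > 0 ? n - 1 : 0);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      cand[m].d2 = dist2_rows(pts, i, pts, j);
      cand[m].idx = j;
      ++m;
    }
    if (k < m)
      std::partial_sort(cand.begin(), cand.begin() + k, cand.begin() + m,
                        cand_less);
    else
      std::sort(cand.begin(), cand.begin() + m, cand_less);
    for (int c = 0; c < k; ++c) {
      idx(i, c) = cand[c].idx + 1;
      dst(i, c) = std::sqrt(cand[c].d2);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// k nearest rows of `pts` for every row of `queries`
// [[Rcpp::export]]
List cpp_knn_query(NumericMatrix pts, NumericMatrix queries, int k) {
  const int n = pts.nrow(), q = queries.nrow();
  if (k > n) k = n;
  IntegerMatrix idx(q, k);
  NumericMatrix dst(q, k);
  std::vector<Cand> cand(n);
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j < n; ++j) {
      cand[j].d2 = dist2_rows(queries, i, pts, j);
      cand[j].idx = j;
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end(), cand_less);
    for (int c = 0; c < k; ++c) {
      idx(i, c) = cand[c].idx + 1;
      dst(i, c) = std::sqrt(cand[c].d2);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// ---------------------------------------------------------------------------
// RANSAC plane fitting
// Plane is {x : n.x + off = 0}, ||n|| = 1, sign canonicalized so the last
// non-zero component of n is positive.

struct PlaneCand {
  double n[3];
  double off;
  long count;
  double sumdist;
  bool ok;
};

static bool plane_from_triple(const NumericMatrix &pts, const int *sub, int a,
                              int b, int c, double scale2, PlaneCand &out) {
  int ia = sub[a], ib = sub[b], ic = sub[c];
  double ux = pts(ib, 0) - pts(ia, 0), uy = pts(ib, 1) - pts(ia, 1),
         uz = pts(ib, 2) - pts(ia, 2);
  double vx = pts(ic, 0) - pts(ia, 0), vy = pts(ic, 1) - pts(ia, 1),
         vz = pts(ic, 2) - pts(ia, 2);
  double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (!(nn > 1e-14 * scale2)) return false;  // (near-)collinear triple
  nx /= nn; ny /= nn; nz /= nn;
  // canonical sign
  if (nz < 0 || (nz == 0 && (ny < 0 || (ny == 0 && nx < 0)))) {
    nx = -nx; ny = -ny; nz = -nz;
  }
  out.n[0] = nx; out.n[1] = ny; out.n[2] = nz;
  out.off = -(nx * pts(ia, 0) + ny * pts(ia, 1) + nz * pts(ia, 2));
  out.ok = true;
  return true;
}

static void score_plane(const NumericMatrix &pts, const int *sub, int m,
                        double eps, PlaneCand &pc) {
  long cnt = 0;
  double sum = 0.0;
  for (int j = 0; j < m; ++j) {
    int pj = sub[j];
    double d = std::fabs(pc.n[0] * pts(pj, 0) + pc.n[1] * pts(pj, 1) +
                         pc.n[2] * pts(pj, 2) + pc.off);
    if (d <= eps) {
      ++cnt;
      sum += d;
    }
  }
  pc.count = cnt;
  pc.sumdist = sum;
}

static inline bool plane_better(const PlaneCand &a, const PlaneCand &b) {
  // more inliers wins; ties by strictly smaller inlier-distance sum;
  // remaining ties keep the earlier candidate (enumeration / draw order)
  if (a.count != b.count) return a.count > b.count;
  return a.sumdist < b.sumdist;
}

// RANSAC over the subset `sub` (m indices into pts). If iters >= C(m,3) all
// triples are enumerated in lexicographic order; otherwise `iters` random
// triples are drawn from mt19937_64(seed). Degenerate triples count against
// the sampling budget but are skipped during enumeration.
static PlaneCand ransac_subset(const NumericMatrix &pts, const int *sub, int m,
                               int iters, double eps, uint64_t seed,
                               double scale2) {
  PlaneCand best;
  best.ok = false;
  best.count = -1;
  best.sumdist = std::numeric_limits<double>::infinity();
  if (m < 3) return best;
  double total = (double)m * (m - 1) * (m - 2) / 6.0;
  PlaneCand cur;
  if ((double)iters >= total) {
    for (int a = 0; a < m - 2; ++a)
      for (int b = a + 1; b < m - 1; ++b)
        for (int c = b + 1; c < m; ++c) {
          if (!plane_from_triple(pts, sub, a, b, c, scale2, cur)) continue;
          score_plane(pts, sub, m, eps, cur);
          if (!best.ok || plane_better(cur, best)) best = cur;
        }
  } else {
    std::mt19937_64 gen(seed);
    for (int it = 0; it < iters; ++it) {
      int a = (int)(gen() % (uint64_t)m);
      int b = (int)(gen() % (uint64_t)m);
      int c = (int)(gen() % (uint64_t)m);
      if (a == b || a == c || b == c) continue;  // counted against budget
      if (!plane_from_triple(pts, sub, a, b, c, scale2, cur)) continue;
      score_plane(pts, sub, m, eps, cur);
      if (!best.ok || plane_better(cur, best)) best = cur;
    }
  }
  return best;
}

static double bbox_diag_subset(const NumericMatrix &pts, const int *sub,
                               int m) {
  double lo[3] = {std::numeric_limits<double>::infinity(),
                  std::numeric_limits<double>::infinity(),
                  std::numeric_limits<double>::infinity()};
  double hi[3] = {-lo[0], -lo[1], -lo[2]};
  for (int j = 0; j < m; ++j)
    for (int d = 0; d < 3; ++d) {
      double v = pts(sub[j], d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  return std::sqrt(sq(hi[0] - lo[0]) + sq(hi[1] - lo[1]) + sq(hi[2] - lo[2]));
}

// [[Rcpp::export]]
List cpp_plane_ransac(NumericMatrix pts, int iters, double eps, double seed) {
  const int n = pts.nrow();
  std::vector<int> sub(n);
  for (int i = 0; i < n; ++i) sub[i] = i;
  double diag = bbox_diag_subset(pts, sub.data(), n);
  PlaneCand best =
      ransac_subset(pts, sub.data(), n, iters, eps, (uint64_t)seed, sq(diag));
  if (!best.ok)
    return List::create(_["ok"] = false);
  NumericVector nrm = NumericVector::create(best.n[0], best.n[1], best.n[2]);
  NumericVector dists(n);
  for (int i = 0; i < n; ++i)
    dists[i] = std::fabs(best.n[0] * pts(i, 0) + best.n[1] * pts(i, 1) +
                         best.n[2] * pts(i, 2) + best.off);
  return List::create(_["ok"] = true, _["normal"] = nrm,
                      _["offset"] = best.off, _["inlier_count"] = (double)best.count,
                      _["sum_inlier_dist"] = best.sumdist, _["dists"] = dists);
}

// Per-point local plane fit: for every point i with knn_idx(i, 0:(count[i]-1))
// neighbours (1-based indices, count < 3 -> NA), fit a RANSAC plane to the
// neighbour set with eps = eps_scale * (neighbour bounding-box diagonal) and
// return the centre point's distance to that plane. Seeded per point.
// [[Rcpp::export]]
NumericVector cpp_local_plane_dists(NumericMatrix pts, IntegerMatrix knn_idx,
                                    IntegerVector counts, int iters,
                                    double eps_scale, double seed) {
  const int n = pts.nrow();
  NumericVector out(n, NA_REAL);
  std::vector<int> sub(knn_idx.ncol());
  for (int i = 0; i < n; ++i) {
    int m = counts[i];
    if (m < 3) continue;
    for (int j = 0; j < m; ++j) sub[j] = knn_idx(i, j) - 1;
    double diag = bbox_diag_subset(pts, sub.data(), m);
    double eps = eps_scale * diag;
    uint64_t s = (uint64_t)seed * 1000003ULL + (uint64_t)i;
    PlaneCand best = ransac_subset(pts, sub.data(), m, iters, eps, s, sq(diag));
    if (!best.ok) continue;
    out[i] = std::fabs(best.n[0] * pts(i, 0) + best.n[1] * pts(i, 1) +
                       best.n[2] * pts(i, 2) + best.off);
  }
  return out;
}

// ---------------------------------------------------------------------------
// PCA normals: 3x3 Jacobi eigensolver, smallest-eigenvalue eigenvector of the
// neighbourhood covariance (neighbourhood = the point itself + its k NN).

static void jacobi3(double a[3][3], double v[3][3], double w[3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) v[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 64; ++sweep) {
    double off = sq(a[0][1]) + sq(a[0][2]) + sq(a[1][2]);
    if (off < 1e-30) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
  }
  for (int i = 0; i < 3; ++i) w[i] = a[i][i];
}

// [[Rcpp::export]]
NumericMatrix cpp_pca_normals(NumericMatrix pts, IntegerMatrix knn_idx) {
  const int n = pts.nrow(), k = knn_idx.ncol();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double mean[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int m = 1;
    for (int c = 0; c < k; ++c) {
      int j = knn_idx(i, c) - 1;
      if (j < 0) break;
      mean[0] += pts(j, 0); mean[1] += pts(j, 1); mean[2] += pts(j, 2);
      ++m;
    }
    mean[0] /= m; mean[1] /= m; mean[2] /= m;
    double cov[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int c = -1; c < k; ++c) {
      int j = (c < 0) ? i : knn_idx(i, c) - 1;
      if (j < 0) break;
      double dx = pts(j, 0) - mean[0], dy = pts(j, 1) - mean[1],
             dz = pts(j, 2) - mean[2];
      cov[0][0] += dx * dx; cov[0][1] += dx * dy; cov[0][2] += dx * dz;
      cov[1][1] += dy * dy; cov[1][2] += dy * dz; cov[2][2] += dz * dz;
    }
    cov[1][0] = cov[0][1]; cov[2][0] = cov[0][2]; cov[2][1] = cov[1][2];
    double v[3][3], w[3];
    jacobi3(cov, v, w);
    int s = 0;
    if (w[1] < w[s]) s = 1;
    if (w[2] < w[s]) s = 2;
    double nx = v[0][s], ny = v[1][s], nz = v[2][s];
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nn < 1e-300) { nx = 0; ny = 0; nz = 1; nn = 1; }
    nx /= nn; ny /= nn; nz /= nn;
    // deterministic provisional sign: largest-magnitude component positive
    double ax = std::fabs(nx), ay = std::fabs(ny), az = std::fabs(nz);
    double lead = (az >= ax && az >= ay) ? nz : (ay >= ax ? ny : nx);
    if (lead < 0) { nx = -nx; ny = -ny; nz = -nz; }
    out(i, 0) = nx; out(i, 1) = ny; out(i, 2) = nz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cell-grid accelerated kNN for dense grid queries (SDF evaluation).

struct CellGrid {
  double lo[3];
  double cell;
  int dims[3];
  std::vector<std::vector<int>> bins;
  const NumericMatrix *pts;

  void build(const NumericMatrix &p) {
    pts = &p;
    const int n = p.nrow();
    double hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::numeric_limits<double>::infinity();
      hi[d] = -lo[d];
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        if (p(i, d) < lo[d]) lo[d] = p(i, d);
        if (p(i, d) > hi[d]) hi[d] = p(i, d);
      }
    double ext[3] = {hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2]};
    double vol = std::max(ext[0], 1e-12) * std::max(ext[1], 1e-12) *
                 std::max(ext[2], 1e-12);
    cell = std::cbrt(vol / std::max(n, 1)) * 2.0;
    double mx = std::max(ext[0], std::max(ext[1], ext[2]));
    if (!(cell > mx * 1e-9)) cell = std::max(mx, 1.0) * 0.1;
    for (int d = 0; d < 3; ++d) {
      dims[d] = std::max(1, (int)std::floor(ext[d] / cell) + 1);
      if (dims[d] > 256) dims[d] = 256;
    }
    // recompute cell so grid covers extent with capped dims
    for (int d = 0; d < 3; ++d)
      cell = std::max(cell, ext[d] / dims[d] + 1e-12);
    bins.assign((size_t)dims[0] * dims[1] * dims[2], {});
    for (int i = 0; i < n; ++i) bins[cell_of(p(i, 0), p(i, 1), p(i, 2))].push_back(i);
  }
  inline int clampi(int v, int hi_) const { return v < 0 ? 0 : (v >= hi_ ? hi_ - 1 : v); }
  inline size_t cell_of(double x, double y, double z) const {
    int cx = clampi((int)std::floor((x - lo[0]) / cell), dims[0]);
    int cy = clampi((int)std::floor((y - lo[1]) / cell), dims[1]);
    int cz = clampi((int)std::floor((z - lo[2]) / cell), dims[2]);
    return ((size_t)cz * dims[1] + cy) * dims[0] + cx;
  }
  // k nearest points to (x,y,z); results appended to cand sorted by (d2, idx)
  void knn(double x, double y, double z, int k, std::vector<Cand> &best) const {
    best.clear();
    int cx = clampi((int)std::floor((x - lo[0]) / cell), dims[0]);
    int cy = clampi((int)std::floor((y - lo[1]) / cell), dims[1]);
    int cz = clampi((int)std::floor((z - lo[2]) / cell), dims[2]);
    int maxr = std::max(dims[0], std::max(dims[1], dims[2]));
    for (int r = 0; r <= maxr; ++r) {
      bool scanned_any = false;
      for (int dz = -r; dz <= r; ++dz) {
        int z_ = cz + dz;
        if (z_ < 0 || z_ >= dims[2]) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int y_ = cy + dy;
          if (y_ < 0 || y_ >= dims[1]) continue;
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;  // only the shell at chebyshev radius r
            int x_ = cx + dx;
            if (x_ < 0 || x_ >= dims[0]) continue;
            scanned_any = true;
            const std::vector<int> &bin =
                bins[((size_t)z_ * dims[1] + y_) * dims[0] + x_];
            for (int idx : bin) {
              Cand c;
              c.d2 = sq((*pts)(idx, 0) - x) + sq((*pts)(idx, 1) - y) +
                     sq((*pts)(idx, 2) - z);
              c.idx = idx;
              auto pos = std::lower_bound(best.begin(), best.end(), c, cand_less);
              if ((int)best.size() < k || pos != best.end()) {
                best.insert(pos, c);
                if ((int)best.size() > k) best.pop_back();
              }
            }
          }
        }
      }
      if ((int)best.size() >= k && best.back().d2 <= sq((double)r * cell)) break;
      if (!scanned_any && r > maxr) break;
    }
  }
};

// Signed distance field on a regular grid from oriented points: the value at
// a node is the Gaussian-weighted average, over the k nearest points, of the
// signed distance to each point's tangent plane.
// Node order: x fastest, then y, then z (R array order for dims c(nx,ny,nz)).
// [[Rcpp::export]]
NumericVector cpp_sdf_grid(NumericMatrix pts, NumericMatrix normals,
                           NumericVector origin, double spacing,
                           IntegerVector dims, int k) {
  CellGrid grid;
  grid.build(pts);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<Cand> best;
  best.reserve(k + 8);
  R_xlen_t at = 0;
  for (int iz = 0; iz < nz; ++iz) {
    double z = origin[2] + iz * spacing;
    for (int iy = 0; iy < ny; ++iy) {
      double y = origin[1] + iy * spacing;
      for (int ix = 0; ix < nx; ++ix, ++at) {
        double x = origin[0] + ix * spacing;
        grid.knn(x, y, z, k, best);
        int m = (int)best.size();
        double h = std::max(std::sqrt(best[m - 1].d2) * 0.5, spacing * 0.5);
        double wsum = 0.0, ssum = 0.0;
        for (int c = 0; c < m; ++c) {
          int j = best[c].idx;
          double s = normals(j, 0) * (x - pts(j, 0)) +
                     normals(j, 1) * (y - pts(j, 1)) +
                     normals(j, 2) * (z - pts(j, 2));
          double w = std::exp(-best[c].d2 / (2.0 * h * h));
          wsum += w;
          ssum += w * s;
        }
        out[at] = (wsum > 0) ? ssum / wsum : 0.0;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over a regular scalar grid (iso-level 0).
// Each cube is split into 6 tetrahedra sharing the (0,0,0)-(1,1,1) diagonal,
// which keeps faces consistent between neighbouring cubes.

struct MTState {
  std::map<std::pair<int64_t, int64_t>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int mt_vertex(MTState &st, int64_t a, int64_t b, double fa, double fb,
                     const double pa[3], const double pb[3]) {
  const double *qa = pa;
  const double *qb = pb;
  if (a > b) {  // canonical edge orientation so shared edges dedup exactly
    std::swap(a, b);
    std::swap(fa, fb);
    std::swap(qa, qb);
  }
  auto key = std::make_pair(a, b);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double tt = fa / (fa - fb);
  int id = (int)st.vx.size();
  st.vx.push_back(qa[0] + tt * (qb[0] - qa[0]));
  st.vy.push_back(qa[1] + tt * (qb[1] - qa[1]));
  st.vz.push_back(qa[2] + tt * (qb[2] - qa[2]));
  st.edge_vertex[key] = id;
  return id;
}

static void mt_tet(MTState &st, const int64_t id[4], const double f[4],
                   const double p[4][3]) {
  bool neg[4];
  int nneg = 0;
  for (int i = 0; i < 4; ++i) {
    neg[i] = f[i] < 0;
    if (neg[i]) ++nneg;
  }
  if (nneg == 0 || nneg == 4) return;
  int a[4], b[4], na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) (neg[i] ? a[na++] : b[nb++]) = i;
  if (nneg == 1 || nneg == 3) {
    int apex = (nneg == 1) ? a[0] : b[0];
    int o0 = -1, o1 = -1, o2 = -1;
    int c = 0;
    for (int i = 0; i < 4; ++i)
      if (i != apex) (c == 0 ? o0 : (c == 1 ? o1 : o2)) = i, ++c;
    int v0 = mt_vertex(st, id[apex], id[o0], f[apex], f[o0], p[apex], p[o0]);
    int v1 = mt_vertex(st, id[apex], id[o1], f[apex], f[o1], p[apex], p[o1]);
    int v2 = mt_vertex(st, id[apex], id[o2], f[apex], f[o2], p[apex], p[o2]);
    if (v0 != v1 && v1 != v2 && v0 != v2) {
      st.f0.push_back(v0); st.f1.push_back(v1); st.f2.push_back(v2);
    }
  } else {  // 2-2: quad across edges (a0,b0),(a0,b1),(a1,b1),(a1,b0)
    int v00 = mt_vertex(st, id[a[0]], id[b[0]], f[a[0]], f[b[0]], p[a[0]], p[b[0]]);
    int v01 = mt_vertex(st, id[a[0]], id[b[1]], f[a[0]], f[b[1]], p[a[0]], p[b[1]]);
    int v11 = mt_vertex(st, id[a[1]], id[b[1]], f[a[1]], f[b[1]], p[a[1]], p[b[1]]);
    int v10 = mt_vertex(st, id[a[1]], id[b[0]], f[a[1]], f[b[0]], p[a[1]], p[b[0]]);
    if (v00 != v01 && v01 != v11 && v00 != v11) {
      st.f0.push_back(v00); st.f1.push_back(v01); st.f2.push_back(v11);
    }
    if (v00 != v11 && v11 != v10 && v00 != v10) {
      st.f0.push_back(v00); st.f1.push_back(v11); st.f2.push_back(v10);
    }
  }
}

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto node = [&](int x, int y, int z) -> int64_t {
    return ((int64_t)z * ny + y) * nx + x;
  };
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  static const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                   {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  MTState st;
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int64_t cid[8];
        double cf[8], cp[8][3];
        bool anyneg = false, anypos = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + corner[c][0], cy = y + corner[c][1], cz = z + corner[c][2];
          cid[c] = node(cx, cy, cz);
          cf[c] = field[cid[c]];
          cp[c][0] = origin[0] + cx * spacing;
          cp[c][1] = origin[1] + cy * spacing;
          cp[c][2] = origin[2] + cz * spacing;
          if (cf[c] < 0) anyneg = true; else anypos = true;
        }
        if (!anyneg || !anypos) continue;
        for (int t = 0; t < 6; ++t) {
          int64_t id[4];
          double f[4], p[4][3];
          for (int v = 0; v < 4; ++v) {
            int c = tets[t][v];
            id[v] = cid[c];
            f[v] = cf[c];
            p[v][0] = cp[c][0]; p[v][1] = cp[c][1]; p[v][2] = cp[c][2];
          }
          mt_tet(st, id, f, p);
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.f0[i] + 1; F(i, 1) = st.f1[i] + 1; F(i, 2) = st.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Unsigned point-to-mesh distance (nearest point on any triangle).
// Closest point on triangle after Ericson, "Real-Time Collision Detection".

static double point_tri_dist2(const double p[3], const double a[3],
                              const double b[3], const double c[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double qx, qy, qz;
  if (d1 <= 0 && d2 <= 0) { qx = a[0]; qy = a[1]; qz = a[2]; goto done; }
  {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) { qx = b[0]; qy = b[1]; qz = b[2]; goto done; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double v = d1 / (d1 - d3);
      qx = a[0] + v * ab[0]; qy = a[1] + v * ab[1]; qz = a[2] + v * ab[2];
      goto done;
    }
    double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d6 >= 0 && d5 <= d6) { qx = c[0]; qy = c[1]; qz = c[2]; goto done; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double w = d2 / (d2 - d6);
      qx = a[0] + w * ac[0]; qy = a[1] + w * ac[1]; qz = a[2] + w * ac[2];
      goto done;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      qx = b[0] + w * (c[0] - b[0]);
      qy = b[1] + w * (c[1] - b[1]);
      qz = b[2] + w * (c[2] - b[2]);
      goto done;
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    qx = a[0] + ab[0] * v + ac[0] * w;
    qy = a[1] + ab[1] * v + ac[1] * w;
    qz = a[2] + ab[2] * v + ac[2] * w;
  }
done:
  return sq(p[0] - qx) + sq(p[1] - qy) + sq(p[2] - qz);
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix V,
                                  IntegerMatrix F) {
  const int n = pts.nrow(), nf = F.nrow();
  // per-face bounding boxes for pruning
  std::vector<double> blo(3 * nf), bhi(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      double v0 = V(ia, d), v1 = V(ib, d), v2 = V(ic, d);
      blo[3 * f + d] = std::min(v0, std::min(v1, v2));
      bhi[3 * f + d] = std::max(v0, std::max(v1, v2));
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      double bd2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double lo = blo[3 * f + d], hi = bhi[3 * f + d];
        if (p[d] < lo) bd2 += sq(lo - p[d]);
        else if (p[d] > hi) bd2 += sq(p[d] - hi);
      }
      if (bd2 >= best) continue;
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
      double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
      double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
      double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// First-hit ray-mesh intersection (Moeller-Trumbore, no backface culling).
// [[Rcpp::export]]
List cpp_ray_mesh_first_hit(NumericMatrix origins, NumericMatrix dirs,
                            NumericMatrix V, IntegerMatrix F) {
  const int nr = origins.nrow(), nf = F.nrow();
  NumericVector tout(nr, NA_REAL);
  IntegerVector fout(nr, NA_INTEGER);
  NumericMatrix hits(nr, 3);
  std::fill(hits.begin(), hits.end(), NA_REAL);
  for (int i = 0; i < nr; ++i) {
    double o[3] = {origins(i, 0), origins(i, 1), origins(i, 2)};
    double d[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    double bt = std::numeric_limits<double>::infinity();
    int bf = -1;
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double e1[3] = {V(ib, 0) - V(ia, 0), V(ib, 1) - V(ia, 1), V(ib, 2) - V(ia, 2)};
      double e2[3] = {V(ic, 0) - V(ia, 0), V(ic, 1) - V(ia, 1), V(ic, 2) - V(ia, 2)};
      double pv[3] = {d[1] * e2[2] - d[2] * e2[1], d[2] * e2[0] - d[0] * e2[2],
                      d[0] * e2[1] - d[1] * e2[0]};
      double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      double tv[3] = {o[0] - V(ia, 0), o[1] - V(ia, 1), o[2] - V(ia, 2)};
      double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1], tv[2] * e1[0] - tv[0] * e1[2],
                      tv[0] * e1[1] - tv[1] * e1[0]};
      double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
      if (t > 1e-9 && t < bt) { bt = t; bf = f; }
    }
    if (bf >= 0) {
      tout[i] = bt;
      fout[i] = bf + 1;
      hits(i, 0) = o[0] + bt * d[0];
      hits(i, 1) = o[1] + bt * d[1];
      hits(i, 2) = o[2] + bt * d[2];
    }
  }
  return List::create(_["t"] = tout, _["face"] = fout, _["points"] = hits);
}
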