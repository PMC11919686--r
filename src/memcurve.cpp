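// Compiled kernels: trilinear sampling, separable Gaussian blur, 3D connected
// components, grid-hash neighbor queries, Monge-patch curvature fits, cyclic
// symmetrization and the cylindrical autocovariance used by the symmetry search.
// All physical coordinates are Angstrom; voxel indices are 0-based with x the
// fastest axis (vol[i + nx*(j + ny*k)]).

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at fractional 0-based voxel indices.
// Out-of-grid queries return `fill` (NA by default from the R wrapper).
static inline double trilin(const double* v, int nx, int ny, int nz,
                            double x, double y, double z,
                            double fill, bool& inside) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    inside = false;
    return fill;
  }
  inside = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double c00 = v[vidx(i0, j0, k0, nx, ny)] * (1 - fx) + v[vidx(i0 + 1, j0, k0, nx, ny)] * fx;
  double c10 = v[vidx(i0, j0 + 1, k0, nx, ny)] * (1 - fx) + v[vidx(i0 + 1, j0 + 1, k0, nx, ny)] * fx;
  double c01 = v[vidx(i0, j0, k0 + 1, nx, ny)] * (1 - fx) + v[vidx(i0 + 1, j0, k0 + 1, nx, ny)] * fx;
  double c11 = v[vidx(i0, j0 + 1, k0 + 1, nx, ny)] * (1 - fx) + v[vidx(i0 + 1, j0 + 1, k0 + 1, nx, ny)] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix idx, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  bool inside;
  for (R_xlen_t p = 0; p < n; p++)
    out[p] = trilin(v, nx, ny, nz, idx(p, 0), idx(p, 1), idx(p, 2), fill, inside);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, kernel truncated at 3 sigma, renormalized at edges.
// [[Rcpp::export]]
NumericVector cpp_blur3(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int hw = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * hw + 1);
  for (int t = -hw; t <= hw; t++) ker[t + hw] = std::exp(-0.5 * t * t / (sigma * sigma));
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot);
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(ntot);
  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ax++) {
    int n = dims[ax];
    R_xlen_t s = strides[ax];
    for (int k = 0; k < nz; k++) for (int j = 0; j < ny; j++) for (int i = 0; i < nx; i++) {
      int pos[3] = {i, j, k};
      R_xlen_t base = vidx(i, j, k, nx, ny);
      double acc = 0, wsum = 0;
      int c = pos[ax];
      int lo = std::max(0, c - hw), hi = std::min(n - 1, c + hw);
      for (int t = lo; t <= hi; t++) {
        double w = ker[t - c + hw];
        acc += w * buf[base + (R_xlen_t)(t - c) * s];
        wsum += w;
      }
      tmp[base] = acc / wsum;
    }
    buf.swap(tmp);
  }
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Voxels of a mask with at least one 6-neighbor outside the mask (the volume
// boundary counts as outside). Returns 0-based (i,j,k) rows.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_voxels(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* m = mask.begin();
  std::vector<int> rows;
  for (int k = 0; k < nz; k++) for (int j = 0; j < ny; j++) for (int i = 0; i < nx; i++) {
    if (!m[vidx(i, j, k, nx, ny)]) continue;
    bool b = i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1;
    if (!b) {
      b = !m[vidx(i - 1, j, k, nx, ny)] || !m[vidx(i + 1, j, k, nx, ny)] ||
          !m[vidx(i, j - 1, k, nx, ny)] || !m[vidx(i, j + 1, k, nx, ny)] ||
          !m[vidx(i, j, k - 1, nx, ny)] || !m[vidx(i, j, k + 1, nx, ny)];
    }
    if (b) { rows.push_back(i); rows.push_back(j); rows.push_back(k); }
  }
  int n = rows.size() / 3;
  IntegerMatrix out(n, 3);
  for (int p = 0; p < n; p++) {
    out(p, 0) = rows[3 * p]; out(p, 1) = rows[3 * p + 1]; out(p, 2) = rows[3 * p + 2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling of a binary mask (6- or 26-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot);
  const int* m = mask.begin();
  std::vector<std::array<int, 3>> offs;
  for (int dk = -1; dk <= 1; dk++) for (int dj = -1; dj <= 1; dj++) for (int di = -1; di <= 1; di++) {
    if (di == 0 && dj == 0 && dk == 0) continue;
    int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
    if (connectivity == 6 && manh > 1) continue;
    offs.push_back({di, dj, dk});
  }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < ntot; s++) {
    if (!m[s] || lab[s]) continue;
    cur++;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = p % nx, j = (p / nx) % ny, k = p / ((R_xlen_t)nx * ny);
      for (auto& o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t q = vidx(ii, jj, kk, nx, ny);
        if (m[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Uniform-grid spatial hash for radius queries on point sets.
struct PointGrid {
  double cell;
  std::unordered_map<uint64_t, std::vector<int>> cells;
  const NumericMatrix& pts;
  PointGrid(const NumericMatrix& p, double cell_size) : cell(cell_size), pts(p) {
    for (int i = 0; i < p.nrow(); i++) cells[key(p(i, 0), p(i, 1), p(i, 2))].push_back(i);
  }
  uint64_t key(double x, double y, double z) const {
    int64_t ix = (int64_t)std::floor(x / cell) + (1 << 20);
    int64_t iy = (int64_t)std::floor(y / cell) + (1 << 20);
    int64_t iz = (int64_t)std::floor(z / cell) + (1 << 20);
    return ((uint64_t)ix << 42) ^ ((uint64_t)iy << 21) ^ (uint64_t)iz;
  }
  // visit indices of points within `r` of (x,y,z)
  template <class F> void visit(double x, double y, double z, double r, F f) const {
    double r2 = r * r;
    int lo[3], hi[3];
    double q[3] = {x, y, z};
    for (int a = 0; a < 3; a++) {
      lo[a] = (int)std::floor((q[a] - r) / cell);
      hi[a] = (int)std::floor((q[a] + r) / cell);
    }
    for (int iz = lo[2]; iz <= hi[2]; iz++) for (int iy = lo[1]; iy <= hi[1]; iy++)
      for (int ix = lo[0]; ix <= hi[0]; ix++) {
        uint64_t k = (((uint64_t)(ix + (1 << 20))) << 42) ^
                     (((uint64_t)(iy + (1 << 20))) << 21) ^ (uint64_t)(iz + (1 << 20));
        auto it = cells.find(k);
        if (it == cells.end()) continue;
        for (int idx : it->second) {
          double dx = pts(idx, 0) - x, dy = pts(idx, 1) - y, dz = pts(idx, 2) - z;
          if (dx * dx + dy * dy + dz * dz <= r2) f(idx);
        }
      }
  }
};

// TRUE where a reference point lies within `cutoff` of the query point.
// [[Rcpp::export]]
LogicalVector cpp_has_neighbor_within(NumericMatrix query, NumericMatrix ref,
                                      double cutoff) {
  PointGrid g(ref, std::max(cutoff, 1e-6));
  LogicalVector out(query.nrow());
  for (int i = 0; i < query.nrow(); i++) {
    bool found = false;
    g.visit(query(i, 0), query(i, 1), query(i, 2), cutoff, [&](int) { found = true; });
    out[i] = found;
  }
  return out;
}

// Greedy minimum-distance thinning in input order: keep a point iff no
// already-kept point lies within min_dist.
// [[Rcpp::export]]
LogicalVector cpp_min_dist_filter(NumericMatrix pts, double min_dist) {
  int n = pts.nrow();
  LogicalVector keep(n);
  double cell = std::max(min_dist, 1e-6);
  std::unordered_map<uint64_t, std::vector<int>> cells;
  auto key = [&](double x, double y, double z) {
    int64_t ix = (int64_t)std::floor(x / cell) + (1 << 20);
    int64_t iy = (int64_t)std::floor(y / cell) + (1 << 20);
    int64_t iz = (int64_t)std::floor(z / cell) + (1 << 20);
    return ((uint64_t)ix << 42) ^ ((uint64_t)iy << 21) ^ (uint64_t)iz;
  };
  double r2 = min_dist * min_dist;
  for (int i = 0; i < n; i++) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    bool clash = false;
    for (int dz = -1; dz <= 1 && !clash; dz++)
      for (int dy = -1; dy <= 1 && !clash; dy++)
        for (int dx = -1; dx <= 1 && !clash; dx++) {
          auto it = cells.find(key(x + dx * cell, y + dy * cell, z + dz * cell));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            double ddx = pts(j, 0) - x, ddy = pts(j, 1) - y, ddz = pts(j, 2) - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz < r2) { clash = true; break; }
          }
        }
    if (!clash) {
      keep[i] = true;
      cells[key(x, y, z)].push_back(i);
    }
  }
  return keep;
}

// ---------------------------------------------------------------------------
// Principal curvatures by local Monge-patch (quadric) fit in the normal-aligned
// frame. Neighbors whose normal disagrees with the center point's normal
// (dot <= min_normal_dot) are excluded so that the two faces of a thin shell
// never mix in one fit. Returns (k1, k2, n_neighbors) per point; curvatures
// in 1/Angstrom.
// [[Rcpp::export]]
NumericMatrix cpp_fit_curvature(NumericMatrix pts, NumericMatrix normals,
                                double radius, int min_neighbors,
                                double min_normal_dot) {
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  PointGrid g(pts, radius);
  for (int i = 0; i < n; i++) {
    std::vector<int> nb;
    g.visit(pts(i, 0), pts(i, 1), pts(i, 2), radius, [&](int j) {
      double dot = normals(i, 0) * normals(j, 0) + normals(i, 1) * normals(j, 1) +
                   normals(i, 2) * normals(j, 2);
      if (dot > min_normal_dot) nb.push_back(j);
    });
    int m = nb.size();
    out(i, 2) = m;
    if (m < min_neighbors) { out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; continue; }
    arma::vec zax = {normals(i, 0), normals(i, 1), normals(i, 2)};
    zax /= arma::norm(zax);
    arma::vec ref = std::abs(zax[0]) < 0.9 ? arma::vec({1, 0, 0}) : arma::vec({0, 1, 0});
    arma::vec e1 = arma::cross(zax, ref); e1 /= arma::norm(e1);
    arma::vec e2 = arma::cross(zax, e1);
    // full quartic height fit: the cubic/quartic columns absorb the
    // higher-order shape (exactly so for spheres and cylinders), removing the
    // truncation bias a pure quadric would fold into the curvature terms;
    // only the quadratic coefficients enter the shape operator. Falls back to
    // the 6-term quadric when the neighborhood is small.
    bool quartic = m >= 25;
    int ncoef = quartic ? 15 : 6;
    arma::mat A(m, ncoef);
    arma::vec h(m);
    for (int t = 0; t < m; t++) {
      arma::vec d = {pts(nb[t], 0) - pts(i, 0), pts(nb[t], 1) - pts(i, 1),
                     pts(nb[t], 2) - pts(i, 2)};
      double u = arma::dot(d, e1), v = arma::dot(d, e2);
      h[t] = arma::dot(d, zax);
      A(t, 0) = u * u; A(t, 1) = u * v; A(t, 2) = v * v;
      A(t, 3) = u; A(t, 4) = v; A(t, 5) = 1.0;
      if (quartic) {
        A(t, 6) = u * u * u; A(t, 7) = u * u * v; A(t, 8) = u * v * v;
        A(t, 9) = v * v * v;
        A(t, 10) = u * u * u * u; A(t, 11) = u * u * u * v;
        A(t, 12) = u * u * v * v; A(t, 13) = u * v * v * v;
        A(t, 14) = v * v * v * v;
      }
    }
    // scale columns for conditioning
    arma::vec colscale(ncoef);
    for (int c = 0; c < ncoef; c++) {
      colscale[c] = arma::norm(A.col(c));
      if (colscale[c] < 1e-12) colscale[c] = 1.0;
      A.col(c) /= colscale[c];
    }
    arma::mat AtA = A.t() * A;
    AtA.diag() += 1e-10;
    arma::vec coef;
    bool ok = arma::solve(coef, AtA, A.t() * h, arma::solve_opts::no_approx);
    if (!ok) { out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; continue; }
    coef /= colscale;
    double a = coef[0], b = coef[1], c = coef[2], p = coef[3], q = coef[4];
    double W = std::sqrt(1.0 + p * p + q * q);
    arma::mat22 II = {{2 * a / W, b / W}, {b / W, 2 * c / W}};
    arma::mat22 I = {{1 + p * p, p * q}, {p * q, 1 + q * q}};
    arma::mat22 S = arma::inv(I) * II;
    double tr = S(0, 0) + S(1, 1);
    double det = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
    double disc = tr * tr / 4.0 - det;
    if (disc < 0) disc = 0;
    double k1 = tr / 2.0 + std::sqrt(disc);
    double k2 = tr / 2.0 - std::sqrt(disc);
    out(i, 0) = k1; out(i, 1) = k2;
  }
  return out;
}

// Neighborhood mean of per-point values (self included), restricted to
// neighbors whose normal agrees with the center's (dot > min_normal_dot).
// Used to average principal curvatures over the local patch before forming
// curvedness, which removes the positive noise bias of the square-root.
// [[Rcpp::export]]
NumericMatrix cpp_neighbor_mean(NumericMatrix pts, NumericMatrix normals,
                                NumericMatrix values, double radius,
                                double min_normal_dot) {
  int n = pts.nrow(), nc = values.ncol();
  NumericMatrix out(n, nc);
  PointGrid g(pts, radius);
  for (int i = 0; i < n; i++) {
    std::vector<double> acc(nc, 0.0);
    int cnt = 0;
    g.visit(pts(i, 0), pts(i, 1), pts(i, 2), radius, [&](int j) {
      double dot = normals(i, 0) * normals(j, 0) + normals(i, 1) * normals(j, 1) +
                   normals(i, 2) * normals(j, 2);
      if (dot <= min_normal_dot) return;
      bool ok = true;
      for (int c = 0; c < nc; c++) if (!R_finite(values(j, c))) { ok = false; break; }
      if (!ok) return;
      for (int c = 0; c < nc; c++) acc[c] += values(j, c);
      cnt++;
    });
    for (int c = 0; c < nc; c++)
      out(i, c) = cnt ? acc[c] / cnt : NA_REAL;
  }
  return out;
}

// Component-wise median of neighbor normals (self excluded), renormalized.
// Returns (mx, my, mz, n_neighbors).
// [[Rcpp::export]]
NumericMatrix cpp_median_normal(NumericMatrix pts, NumericMatrix normals,
                                double radius) {
  int n = pts.nrow();
  NumericMatrix out(n, 4);
  PointGrid g(pts, radius);
  for (int i = 0; i < n; i++) {
    std::vector<int> nb;
    g.visit(pts(i, 0), pts(i, 1), pts(i, 2), radius, [&](int j) {
      if (j != i) nb.push_back(j);
    });
    int m = nb.size();
    out(i, 3) = m;
    if (m == 0) { out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL; continue; }
    double med[3];
    std::vector<double> comp(m);
    for (int a = 0; a < 3; a++) {
      for (int t = 0; t < m; t++) comp[t] = normals(nb[t], a);
      std::nth_element(comp.begin(), comp.begin() + m / 2, comp.end());
      double hi = comp[m / 2];
      if (m % 2 == 0) {
        std::nth_element(comp.begin(), comp.begin() + m / 2 - 1, comp.end());
        med[a] = 0.5 * (hi + comp[m / 2 - 1]);
      } else med[a] = hi;
    }
    double nrm = std::sqrt(med[0] * med[0] + med[1] * med[1] + med[2] * med[2]);
    if (nrm < 1e-12) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
    } else {
      out(i, 0) = med[0] / nrm; out(i, 1) = med[1] / nrm; out(i, 2) = med[2] / nrm;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Average of n copies of the map rotated by rot + k*360/n about the axis
// parallel to z at physical (ax, ay). Voxels with any out-of-grid pre-image
// are excluded via the support mask.
// [[Rcpp::export]]
List cpp_apply_cn(NumericVector vol, IntegerVector dim, double voxel,
                  NumericVector origin, int n, double ax, double ay,
                  double rot_deg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot);
  LogicalVector support(ntot);
  const double* v = vol.begin();
  std::vector<double> ct(n), st(n);
  for (int m = 0; m < n; m++) {
    double th = (rot_deg + m * 360.0 / n) * M_PI / 180.0;
    ct[m] = std::cos(-th); st[m] = std::sin(-th);
  }
  double ox = origin[0], oy = origin[1], oz = origin[2];
  for (int k = 0; k < nz; k++) {
    double pz = oz + k * voxel;
    double zi = (pz - oz) / voxel;
    for (int j = 0; j < ny; j++) {
      double py = oy + j * voxel;
      for (int i = 0; i < nx; i++) {
        double px = ox + i * voxel;
        double rx = px - ax, ry = py - ay;
        double acc = 0;
        bool ok = true, inside;
        for (int m = 0; m < n; m++) {
          double qx = ax + ct[m] * rx - st[m] * ry;
          double qy = ay + st[m] * rx + ct[m] * ry;
          double val = trilin(v, nx, ny, nz, (qx - ox) / voxel, (qy - oy) / voxel,
                              zi, 0.0, inside);
          if (!inside) { ok = false; break; }
          acc += val;
        }
        R_xlen_t p = vidx(i, j, k, nx, ny);
        if (ok) { out[p] = acc / n; support[p] = true; }
        else { out[p] = NA_REAL; support[p] = false; }
      }
    }
  }
  return List::create(_["values"] = out, _["support"] = support);
}

// Rotate a map by `deg` about the z-parallel axis at physical (ax, ay).
// [[Rcpp::export]]
List cpp_rotate_z(NumericVector vol, IntegerVector dim, double voxel,
                  NumericVector origin, double deg, double ax, double ay) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot);
  LogicalVector support(ntot);
  const double* v = vol.begin();
  double th = -deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double ox = origin[0], oy = origin[1], oz = origin[2];
  bool inside;
  for (int k = 0; k < nz; k++) for (int j = 0; j < ny; j++) for (int i = 0; i < nx; i++) {
    double px = ox + i * voxel - ax, py = oy + j * voxel - ay;
    double qx = ax + ct * px - st * py, qy = ay + st * px + ct * py;
    double val = trilin(v, nx, ny, nz, (qx - ox) / voxel, (qy - oy) / voxel,
                        (double)k, 0.0, inside);
    R_xlen_t p = vidx(i, j, k, nx, ny);
    out[p] = inside ? val : NA_REAL;
    support[p] = inside;
  }
  return List::create(_["values"] = out, _["support"] = support);
}

// ---------------------------------------------------------------------------
// Cylindrical resampling shared by the symmetry kernels: samples the map on
// rings (r = (ir+0.5)*dr, theta in ntheta steps, z slices in z_idx) about the
// z-parallel axis at (ax, ay), removes each ring's mean (the axisymmetric
// component carries no cyclic-symmetry information), weights rings by r, and
// optionally zeroes the weight of rings whose residual variance is below
// row_var_factor times the median (empty-solvent mask).
static void cyl_resample(const double* v, int nx, int ny, int nz, double voxel,
                         const double* origin, double ax, double ay, double dr,
                         int nr, int ntheta, const int* z_idx, int nzz,
                         bool mask_rows, double row_var_factor,
                         arma::mat& X, arma::vec& w) {
  double ox = origin[0], oy = origin[1];
  X.set_size(ntheta, (arma::uword)nr * nzz);
  w.set_size((arma::uword)nr * nzz);
  std::vector<double> ct(ntheta), st(ntheta);
  for (int t = 0; t < ntheta; t++) {
    double th = 2.0 * M_PI * t / ntheta;
    ct[t] = std::cos(th); st[t] = std::sin(th);
  }
  bool inside;
  arma::uword col = 0;
  for (int izz = 0; izz < nzz; izz++) {
    double zi = (double)z_idx[izz];
    for (int ir = 0; ir < nr; ir++, col++) {
      double r = (ir + 0.5) * dr;
      w[col] = r;
      double rowsum = 0;
      for (int t = 0; t < ntheta; t++) {
        double px = ax + r * ct[t], py = ay + r * st[t];
        double val = trilin(v, nx, ny, nz, (px - ox) / voxel, (py - oy) / voxel,
                            zi, 0.0, inside);
        X(t, col) = val;
        rowsum += val;
      }
      double rowmean = rowsum / ntheta;
      for (int t = 0; t < ntheta; t++) X(t, col) -= rowmean;
    }
  }
  arma::uword ncols = X.n_cols;
  if (mask_rows && ncols > 4) {
    // soft mask: weight rings by their residual variance in excess of the
    // median (the solvent/noise floor). Variances are smoothed over the
    // (r, z) neighborhood first: signal occupies contiguous rings, noise
    // fluctuations do not survive the averaging.
    arma::vec rv(ncols);
    for (arma::uword c = 0; c < ncols; c++) {
      double s = 0;
      for (int t = 0; t < ntheta; t++) s += X(t, c) * X(t, c);
      rv[c] = s;
    }
    arma::vec rvs(ncols);
    for (int izz = 0; izz < nzz; izz++) for (int ir = 0; ir < nr; ir++) {
      double s = 0; int cnt = 0;
      for (int dz = -1; dz <= 1; dz++) for (int dri = -1; dri <= 1; dri++) {
        int z2 = izz + dz, r2 = ir + dri;
        if (z2 < 0 || z2 >= nzz || r2 < 0 || r2 >= nr) continue;
        s += rv[(arma::uword)z2 * nr + r2];
        cnt++;
      }
      rvs[(arma::uword)izz * nr + ir] = s / cnt;
    }
    double med = arma::median(rvs);
    arma::vec w2 = w;
    for (arma::uword c = 0; c < ncols; c++)
      w2[c] = w[c] * std::max(rvs[c] - row_var_factor * med, 0.0);
    if (arma::accu(w2) > 0) w = w2;  // otherwise nothing stands out; keep all
  }
}

// Correlation of the map with the average of its n-1 non-identity Cn copies,
// computed on the cylindrical resampling. The identity copy is excluded (it
// carries the full voxel noise and would bias the score toward small n) and
// the correlation runs over the azimuths holding signal energy, so a patch
// covering only part of a ring is compared where it has data. Returns one
// score per requested n.
// [[Rcpp::export]]
NumericVector cpp_cyl_symscore(NumericVector vol, IntegerVector dim, double voxel,
                               NumericVector origin, double ax, double ay,
                               double dr, int nr, int ntheta, IntegerVector z_idx,
                               IntegerVector n_values, double rot_deg,
                               bool mask_rows, double row_var_factor,
                               double theta_mask_frac) {
  arma::mat X;
  arma::vec w;
  cyl_resample(vol.begin(), dim[0], dim[1], dim[2], voxel, origin.begin(),
               ax, ay, dr, nr, ntheta, z_idx.begin(), z_idx.size(),
               mask_rows, row_var_factor, X, w);
  arma::uword ncols = X.n_cols;
  // azimuthal energy profile over retained rings -> theta mask
  arma::vec E(ntheta, arma::fill::zeros);
  for (arma::uword c = 0; c < ncols; c++) {
    if (w[c] <= 0) continue;
    for (int t = 0; t < ntheta; t++) E[t] += w[c] * X(t, c) * X(t, c);
  }
  // circular smoothing over +/- 2 azimuth steps before thresholding
  arma::vec Es(ntheta);
  for (int t = 0; t < ntheta; t++) {
    double s = 0;
    for (int dt = -2; dt <= 2; dt++) {
      int u = (t + dt + ntheta) % ntheta;
      s += E[u];
    }
    Es[t] = s / 5.0;
  }
  E = Es;
  double emed = arma::median(E), emax = E.max();
  double thr = emed + theta_mask_frac * std::max(emax - emed, 0.0);
  // azimuth weights: excess energy over the solvent floor (soft mask),
  // keeping azimuths at or above the threshold
  std::vector<int> tmask;
  std::vector<double> tw;
  for (int t = 0; t < ntheta; t++)
    if (E[t] >= thr) {
      tmask.push_back(t);
      tw.push_back(std::max(E[t] - emed, 0.0) + 1e-12);
    }
  if ((int)tmask.size() < 8) {
    tmask.clear(); tw.clear();
    for (int t = 0; t < ntheta; t++) { tmask.push_back(t); tw.push_back(1.0); }
  }
  NumericVector out(n_values.size());
  size_t nt = tmask.size();
  for (int ni = 0; ni < n_values.size(); ni++) {
    int n = n_values[ni];
    // per-copy interpolation offsets (shared across rings and azimuths)
    std::vector<int> ia(n - 1);
    std::vector<double> fr(n - 1);
    for (int k = 1; k < n; k++) {
      double shift = (rot_deg / 360.0 + (double)k / n) * ntheta;
      shift -= ntheta * std::floor(shift / ntheta);
      if (shift >= ntheta) shift -= ntheta;
      ia[k - 1] = (int)std::floor(shift);
      fr[k - 1] = shift - ia[k - 1];
    }
    double inv = 1.0 / (n - 1);
    double sw = 0, sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    for (arma::uword c = 0; c < ncols; c++) {
      if (w[c] <= 0) continue;
      const double* xc = X.colptr(c);
      for (size_t ti = 0; ti < nt; ti++) {
        int t = tmask[ti];
        // average of the n-1 non-identity copies at this azimuth
        double s = 0;
        for (int k = 0; k < n - 1; k++) {
          int a = t + ia[k]; if (a >= ntheta) a -= ntheta;
          int b = a + 1; if (b >= ntheta) b -= ntheta;
          s += (1 - fr[k]) * xc[a] + fr[k] * xc[b];
        }
        double xv = xc[t], yv = s * inv, ww = w[c] * tw[ti];
        sw += ww; sx += ww * xv; sy += ww * yv;
        sxx += ww * xv * xv; syy += ww * yv * yv; sxy += ww * xv * yv;
      }
    }
    double vx = sxx - sx * sx / sw, vy = syy - sy * sy / sw;
    double cv = sxy - sx * sy / sw;
    out[ni] = (vx > 0 && vy > 0) ? cv / std::sqrt(vx * vy) : 0.0;
  }
  return out;
}

// Weighted circular autocovariance over the azimuth of a cylindrical resampling
// of the map about the z-parallel axis at physical (ax, ay). Radial rings at
// r = (ir + 0.5) * dr, ir < nr; azimuth in ntheta uniform steps; all z slices
// in z_idx (0-based). Samples outside the grid count as zero density (the
// particle is assumed fully contained). Ring weight is r (annulus measure).
// The mean of each (r, z) ring is removed before correlating, discarding the
// axisymmetric component, which carries no cyclic-symmetry information but
// would otherwise add a lag-independent baseline. With mask_rows, rings whose
// residual variance is below `row_var_factor` times the median ring variance
// are dropped (a data-driven mask restricting the correlation to the
// radial-axial band holding the particle, instead of empty solvent).
// Returns `acov` (lag = 0..ntheta-1), the azimuthal energy profile
// `energy[theta]` = weighted squared residual per azimuth (whose circular
// autocovariance measures how much signal support two lags share), and the
// number of rings used.
// [[Rcpp::export]]
List cpp_cyl_autocov(NumericVector vol, IntegerVector dim, double voxel,
                     NumericVector origin, double ax, double ay,
                     double dr, int nr, int ntheta, IntegerVector z_idx,
                     bool mask_rows, double row_var_factor) {
  arma::mat X;
  arma::vec w;
  cyl_resample(vol.begin(), dim[0], dim[1], dim[2], voxel, origin.begin(),
               ax, ay, dr, nr, ntheta, z_idx.begin(), z_idx.size(),
               mask_rows, row_var_factor, X, w);
  arma::uword ncols = X.n_cols;
  arma::cx_mat F = arma::fft(X);
  arma::cx_vec spec(ntheta, arma::fill::zeros);
  NumericVector energy(ntheta);
  int rows_used = 0;
  for (arma::uword c = 0; c < ncols; c++) {
    if (w[c] <= 0) continue;
    rows_used++;
    spec += w[c] * (F.col(c) % arma::conj(F.col(c)));
  }
  for (int t = 0; t < ntheta; t++) {
    double e = 0;
    for (arma::uword c = 0; c < ncols; c++)
      if (w[c] > 0) e += w[c] * X(t, c) * X(t, c);
    energy[t] = e;
  }
  arma::cx_vec ac = arma::ifft(spec);
  NumericVector out(ntheta);
  for (int t = 0; t < ntheta; t++) out[t] = ac[t].real();
  return List::create(_["acov"] = out, _["energy"] = energy,
                      _["rows_used"] = rows_used);
}
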