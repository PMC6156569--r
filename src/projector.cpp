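#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joseph-style line integrals through a voxel volume holding K scalar
// components per voxel, stored component-fastest
// (idx = k + K*(x + nx*(y + ny*z))) so the K-loop is contiguous.
// The ray is parameterized slice-by-slice along its dominant axis; at each
// slice the remaining two coordinates are interpolated bilinearly and the
// slice contributes pathlength h_major/|d_major|. Voxels outside the grid
// contribute zero (no clamping), so a ray missing the volume integrates to 0.
// Exact for axis-aligned rays through voxel centers.

static inline void other_axes(int a, int &b, int &c) {
  if (a == 0) { b = 1; c = 2; }
  else if (a == 1) { b = 0; c = 2; }
  else { b = 0; c = 1; }
}

// [[Rcpp::export]]
NumericMatrix cpp_ray_integrals(NumericVector vol, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix p0s, NumericVector dir) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], K = dims[3];
  const int n[3] = {nx, ny, nz};
  const int nrays = p0s.nrow();
  double d[3] = {dir[0], dir[1], dir[2]};

  int a = 0;
  if (std::fabs(d[1]) > std::fabs(d[a])) a = 1;
  if (std::fabs(d[2]) > std::fabs(d[a])) a = 2;
  int b, c;
  other_axes(a, b, c);

  const double ha = spacing[a], hb = spacing[b], hc = spacing[c];
  const double oa = origin[a], ob = origin[b], oc = origin[c];
  const double L = ha / std::fabs(d[a]);  // path length per slice

  const double *v = REAL(vol);
  NumericMatrix out(nrays, K);
  std::vector<double> acc(K);

  for (int r = 0; r < nrays; ++r) {
    const double p0[3] = {p0s(r, 0), p0s(r, 1), p0s(r, 2)};
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < n[a]; ++i) {
      const double xa = oa + (i + 0.5) * ha;
      const double t = (xa - p0[a]) / d[a];
      const double fb = (p0[b] + t * d[b] - ob) / hb - 0.5;
      const double fc = (p0[c] + t * d[c] - oc) / hc - 0.5;
      const int ib0 = (int)std::floor(fb), ic0 = (int)std::floor(fc);
      const double wb1 = fb - ib0, wc1 = fc - ic0;
      for (int db = 0; db <= 1; ++db) {
        const int ib = ib0 + db;
        if (ib < 0 || ib >= n[b]) continue;
        const double wb = db ? wb1 : 1.0 - wb1;
        for (int dc = 0; dc <= 1; ++dc) {
          const int ic = ic0 + dc;
          if (ic < 0 || ic >= n[c]) continue;
          const double w = wb * (dc ? wc1 : 1.0 - wc1) * L;
          if (w == 0.0) continue;
          int ijk[3];
          ijk[a] = i; ijk[b] = ib; ijk[c] = ic;
          const double *vv = v + (size_t)K * (ijk[0] + nx * (ijk[1] + ny * ijk[2]));
          for (int k = 0; k < K; ++k)
            acc[k] += w * vv[k];
        }
      }
    }
    for (int k = 0; k < K; ++k) out(r, k) = acc[k];
  }
  return out;
}

// Exact transpose of cpp_ray_integrals followed by the weight contraction
// p_r = sum_k w_k * I_{rk}: scatters y_r * w_k through the same bilinear
// footprint into the accumulator volume `vol` (component-fastest layout,
// modified in place; the caller owns the allocation).
// [[Rcpp::export]]
void cpp_backproject_rays(NumericVector vol, IntegerVector dims,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix p0s, NumericVector dir,
                          NumericVector weights, NumericVector y) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], K = dims[3];
  const int n[3] = {nx, ny, nz};
  const int nrays = p0s.nrow();
  double d[3] = {dir[0], dir[1], dir[2]};

  int a = 0;
  if (std::fabs(d[1]) > std::fabs(d[a])) a = 1;
  if (std::fabs(d[2]) > std::fabs(d[a])) a = 2;
  int b, c;
  other_axes(a, b, c);

  const double ha = spacing[a], hb = spacing[b], hc = spacing[c];
  const double oa = origin[a], ob = origin[b], oc = origin[c];
  const double L = ha / std::fabs(d[a]);

  double *v = REAL(vol);

  for (int r = 0; r < nrays; ++r) {
    const double yr = y[r];
    if (yr == 0.0) continue;
    const double p0[3] = {p0s(r, 0), p0s(r, 1), p0s(r, 2)};
    for (int i = 0; i < n[a]; ++i) {
      const double xa = oa + (i + 0.5) * ha;
      const double t = (xa - p0[a]) / d[a];
      const double fb = (p0[b] + t * d[b] - ob) / hb - 0.5;
      const double fc = (p0[c] + t * d[c] - oc) / hc - 0.5;
      const int ib0 = (int)std::floor(fb), ic0 = (int)std::floor(fc);
      const double wb1 = fb - ib0, wc1 = fc - ic0;
      for (int db = 0; db <= 1; ++db) {
        const int ib = ib0 + db;
        if (ib < 0 || ib >= n[b]) continue;
        const double wb = db ? wb1 : 1.0 - wb1;
        for (int dc = 0; dc <= 1; ++dc) {
          const int ic = ic0 + dc;
          if (ic < 0 || ic >= n[c]) continue;
          const double w = wb * (dc ? wc1 : 1.0 - wc1) * L;
          if (w == 0.0) continue;
          int ijk[3];
          ijk[a] = i; ijk[b] = ib; ijk[c] = ic;
          double *vv = v + (size_t)K * (ijk[0] + nx * (ijk[1] + ny * ijk[2]));
          const double wyr = yr * w;
          for (int k = 0; k < K; ++k)
            vv[k] += wyr * weights[k];
        }
      }
    }
  }
}
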