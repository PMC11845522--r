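#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
// pts is 3 x n; points outside the grid get `background`.
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector vol, IntegerVector dims,
                               NumericMatrix pts, double background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.ncol();
  NumericVector out(n);
  const double *v = vol.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int p = 0; p < n; ++p) {
    double x = pts(0, p), y = pts(1, p), z = pts(2, p);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1 ||
        ISNAN(x) || ISNAN(y) || ISNAN(z)) {
      out[p] = background;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    // degenerate single-slab axes: clamp to 0
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    const double *b = v + i0 * sx + j0 * sy + k0 * sz;
    double c00 = b[0] * (1 - fx) + b[sx] * fx;
    double c10 = b[sy] * (1 - fx) + b[sy + sx] * fx;
    double c01 = b[sz] * (1 - fx) + b[sz + sx] * fx;
    double c11 = b[sz + sy] * (1 - fx) + b[sz + sy + sx] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Joint histogram with linear (partial-volume) bin interpolation, the
// continuous binning used by Mattes-style mutual information. Values are
// mapped to [0, bins-1] via (v - lo) / width and mass split between the two
// neighbouring bins; out-of-range values are clamped to the edge bins.
// [[Rcpp::export(name = ".joint_hist_pv")]]
NumericMatrix joint_hist_pv(NumericVector a, NumericVector b, int bins,
                            double alo, double awidth, double blo, double bwidth) {
  const int n = a.size();
  NumericMatrix h(bins, bins);
  for (int p = 0; p < n; ++p) {
    double u = (a[p] - alo) / awidth;
    double w = (b[p] - blo) / bwidth;
    if (u < 0) u = 0;
    if (w < 0) w = 0;
    if (u > bins - 1) u = bins - 1;
    if (w > bins - 1) w = bins - 1;
    int i0 = (int)std::floor(u);
    int j0 = (int)std::floor(w);
    if (i0 == bins - 1) i0--;
    if (j0 == bins - 1) j0--;
    double fu = u - i0, fw = w - j0;
    h(i0, j0)         += (1 - fu) * (1 - fw);
    h(i0 + 1, j0)     += fu * (1 - fw);
    h(i0, j0 + 1)     += (1 - fu) * fw;
    h(i0 + 1, j0 + 1) += fu * fw;
  }
  return h;
}

// Minimum Euclidean distance from each query point (3 x n) to a polyline
// given by its vertices (3 x m), treating the polyline as a chain of
// segments. Used for tube-shaped signed-distance geometry (cochlear spiral).
// [[Rcpp::export(name = ".dist_to_polyline")]]
NumericVector dist_to_polyline(NumericMatrix pts, NumericMatrix verts) {
  const int n = pts.ncol(), m = verts.ncol();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double px = pts(0, p), py = pts(1, p), pz = pts(2, p);
    double best = R_PosInf;
    for (int s = 0; s + 1 < m; ++s) {
      double ax = verts(0, s), ay = verts(1, s), az = verts(2, s);
      double dx = verts(0, s + 1) - ax, dy = verts(1, s + 1) - ay,
             dz = verts(2, s + 1) - az;
      double len2 = dx * dx + dy * dy + dz * dz;
      double t = 0.0;
      if (len2 > 0) {
        t = ((px - ax) * dx + (py - ay) * dy + (pz - az) * dz) / len2;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
      }
      double ex = px - (ax + t * dx), ey = py - (ay + t * dy),
             ez = pz - (az + t * dz);
      double d2 = ex * ex + ey * ey + ez * ez;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
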