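// Gamma-index kernels.
//
// Both kernels minimise, over a local fine lattice of candidate positions
// centred on each reference point,
//     gamma^2 = ((D_eval(c) - D_ref(p)) / dd_abs)^2 + (|c - p| / dc)^2
// where dd_abs is the absolute (global) dose criterion in Gy and dc the
// distance criterion in mm.  The candidate lattice is the set of offsets
// k*step per axis with |k| <= floor(radius/step + 1e-9) and Euclidean norm
// <= radius + 1e-9; the evaluated distribution is interpolated (bi/tri-
// linearly) at each candidate.  Offsets are visited in order of increasing
// distance so the search can stop as soon as the distance term alone
// exceeds the current best gamma^2; the minimiser over the identical
// candidate set is unchanged by this pruning.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Off2 { double dr, dc, d2; };
struct Off3 { double dx, dy, dz, d2; };

inline double wrap_mod(double x, double period) {
  double r = x - std::floor(x / period) * period;
  if (r >= period) r -= period;  // guard against rounding at the seam
  if (r < 0) r = 0;
  return r;
}

// Bilinear interpolation on a detector map.  Rows are axial (coordinate
// r = (i)*row_sp, i 0-based, clipped), columns azimuthal (c = j*col_sp,
// wrapped modulo the circumference when wrap is true).  Returns false when
// the position is outside the map.
inline bool interp2(const NumericMatrix& v, double row_sp, double col_sp,
                    bool wrap, double r, double c, double* out) {
  const int nr = v.nrow(), nc = v.ncol();
  const double eps = 1e-9;
  double fi = r / row_sp;
  if (fi < -eps || fi > nr - 1 + eps) return false;
  fi = std::min(std::max(fi, 0.0), (double)(nr - 1));
  int i0 = (int)std::floor(fi);
  if (i0 > nr - 2) i0 = nr - 2;
  if (i0 < 0) i0 = 0;
  int i1 = std::min(i0 + 1, nr - 1);
  double ti = fi - i0;

  double tj;
  int j0, j1;
  if (wrap) {
    double circ = nc * col_sp;
    double cw = wrap_mod(c, circ);
    double fj = cw / col_sp;
    int jf = (int)std::floor(fj);
    tj = fj - jf;
    j0 = jf % nc;
    j1 = (j0 + 1) % nc;
  } else {
    double fj = c / col_sp;
    if (fj < -eps || fj > nc - 1 + eps) return false;
    fj = std::min(std::max(fj, 0.0), (double)(nc - 1));
    j0 = (int)std::floor(fj);
    if (j0 > nc - 2) j0 = nc - 2;
    if (j0 < 0) j0 = 0;
    j1 = std::min(j0 + 1, nc - 1);
    tj = fj - j0;
  }
  double val = v(i0, j0) * (1 - ti) * (1 - tj) + v(i1, j0) * ti * (1 - tj) +
               v(i0, j1) * (1 - ti) * tj       + v(i1, j1) * ti * tj;
  *out = val;
  return true;
}

inline bool interp3(const double* v, const int* d, const double* sp,
                    double x, double y, double z, double* out) {
  const double eps = 1e-9;
  double f[3] = { x / sp[0], y / sp[1], z / sp[2] };
  int i0[3], i1[3];
  double t[3];
  for (int a = 0; a < 3; ++a) {
    if (f[a] < -eps || f[a] > d[a] - 1 + eps) return false;
    double fa = std::min(std::max(f[a], 0.0), (double)(d[a] - 1));
    int lo = (int)std::floor(fa);
    if (lo > d[a] - 2) lo = d[a] - 2;
    if (lo < 0) lo = 0;
    i0[a] = lo;
    i1[a] = std::min(lo + 1, d[a] - 1);
    t[a] = fa - lo;
  }
  const int n1 = d[0], n12 = d[0] * d[1];
  double acc = 0.0;
  for (int cz = 0; cz < 2; ++cz)
    for (int cy = 0; cy < 2; ++cy)
      for (int cx = 0; cx < 2; ++cx) {
        int ix = cx ? i1[0] : i0[0];
        int iy = cy ? i1[1] : i0[1];
        int iz = cz ? i1[2] : i0[2];
        double w = (cx ? t[0] : 1 - t[0]) * (cy ? t[1] : 1 - t[1]) *
                   (cz ? t[2] : 1 - t[2]);
        acc += w * v[ix + n1 * iy + n12 * iz];
      }
  *out = acc;
  return true;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix gamma_2d_cpp(NumericMatrix ref, NumericMatrix eval,
                           double row_sp, double col_sp, bool wrap,
                           double dd_abs, double dc, double step,
                           double radius, LogicalMatrix evaluated) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const int K = (int)std::floor(radius / step + 1e-9);
  std::vector<Off2> offs;
  for (int a = -K; a <= K; ++a)
    for (int b = -K; b <= K; ++b) {
      double dr = a * step, dco = b * step;
      double d2 = dr * dr + dco * dco;
      if (std::sqrt(d2) <= radius + 1e-9) offs.push_back({dr, dco, d2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Off2& u, const Off2& v) { return u.d2 < v.d2; });
  const double dc2 = dc * dc;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!evaluated(i, j)) continue;
      const double dref = ref(i, j);
      const double r0 = i * row_sp, c0 = j * col_sp;
      double best = R_PosInf;
      for (const Off2& o : offs) {
        double dist_term = o.d2 / dc2;
        if (dist_term >= best) break;
        double de;
        if (!interp2(eval, row_sp, col_sp, wrap, r0 + o.dr, c0 + o.dc, &de))
          continue;
        double dd = (de - dref) / dd_abs;
        double g2 = dd * dd + dist_term;
        if (g2 < best) best = g2;
      }
      if (R_finite(best)) out(i, j) = std::sqrt(best);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector gamma_3d_cpp(NumericVector ref, NumericVector eval,
                           IntegerVector dims, NumericVector spacing,
                           double dd_abs, double dc, double step,
                           double radius, LogicalVector evaluated) {
  const int d[3] = { dims[0], dims[1], dims[2] };
  const double sp[3] = { spacing[0], spacing[1], spacing[2] };
  const int K = (int)std::floor(radius / step + 1e-9);
  std::vector<Off3> offs;
  for (int a = -K; a <= K; ++a)
    for (int b = -K; b <= K; ++b)
      for (int c = -K; c <= K; ++c) {
        double dx = a * step, dy = b * step, dz = c * step;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (std::sqrt(d2) <= radius + 1e-9) offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off3& u, const Off3& v) { return u.d2 < v.d2; });
  const double dc2 = dc * dc;
  const double* ev = REAL(eval);
  const double* rv = REAL(ref);
  const int n = ref.size();
  NumericVector out(n, NA_REAL);
  for (int idx = 0; idx < n; ++idx) {
    if (!evaluated[idx]) continue;
    int ix = idx % d[0];
    int iy = (idx / d[0]) % d[1];
    int iz = idx / (d[0] * d[1]);
    double x0 = ix * sp[0], y0 = iy * sp[1], z0 = iz * sp[2];
    double dref = rv[idx];
    double best = R_PosInf;
    for (const Off3& o : offs) {
      double dist_term = o.d2 / dc2;
      if (dist_term >= best) break;
      double de;
      if (!interp3(ev, d, sp, x0 + o.dx, y0 + o.dy, z0 + o.dz, &de)) continue;
      double dd = (de - dref) / dd_abs;
      double g2 = dd * dd + dist_term;
      if (g2 < best) best = g2;
    }
    if (R_finite(best)) out[idx] = std::sqrt(best);
  }
  out.attr("dim") = dims;
  return out;
}
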