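#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// bilinear interpolant of a grid matrix at continuous index coords (u, v);
// u in [0, na-1] along rows (mu_a axis), v in [0, ns-1] along cols
struct Bilinear {
  const NumericMatrix& M;
  int na, ns;
  explicit Bilinear(const NumericMatrix& m) : M(m), na(m.nrow()), ns(m.ncol()) {}
  inline void cell(double u, double v, int& i, int& j, double& fu, double& fv) const {
    i = static_cast<int>(std::floor(u)); if (i > na - 2) i = na - 2; if (i < 0) i = 0;
    j = static_cast<int>(std::floor(v)); if (j > ns - 2) j = ns - 2; if (j < 0) j = 0;
    fu = u - i; fv = v - j;
  }
  inline double value(double u, double v) const {
    int i, j; double fu, fv; cell(u, v, i, j, fu, fv);
    return M(i, j) * (1 - fu) * (1 - fv) + M(i + 1, j) * fu * (1 - fv)
         + M(i, j + 1) * (1 - fu) * fv + M(i + 1, j + 1) * fu * fv;
  }
  inline double du(double u, double v) const {
    int i, j; double fu, fv; cell(u, v, i, j, fu, fv);
    return (M(i + 1, j) - M(i, j)) * (1 - fv) + (M(i + 1, j + 1) - M(i, j + 1)) * fv;
  }
  inline double dv(double u, double v) const {
    int i, j; double fu, fv; cell(u, v, i, j, fu, fv);
    return (M(i, j + 1) - M(i, j)) * (1 - fu) + (M(i + 1, j + 1) - M(i + 1, j)) * fu;
  }
};

inline double interp_axis(const NumericVector& g, double u) {
  int n = g.size();
  int i = static_cast<int>(std::floor(u));
  if (i > n - 2) i = n - 2; if (i < 0) i = 0;
  return g[i] + (u - i) * (g[i + 1] - g[i]);
}

} // namespace

// Inverse interpolation of the two-frequency LUT image: for each query pair
// (rd1, rd2), find continuous grid coordinates where the bilinear forward
// surfaces match the target (damped Newton seeded at the nearest node of a
// coarse sub-grid). Queries whose forward residual cannot be driven below
// rel_tol (targets outside the LUT image hull) are flagged out-of-domain.
// Columns of the result: mu_a, mu_s_prime, residual (2-norm), in_domain flag.
// [[Rcpp::export]]
NumericMatrix lut_invert_cpp(NumericVector rd1, NumericVector rd2,
                             NumericVector mu_a_grid, NumericVector mu_s_grid,
                             NumericMatrix rd_low, NumericMatrix rd_high,
                             double rel_tol) {
  const int nq = rd1.size();
  const int na = mu_a_grid.size(), ns = mu_s_grid.size();
  Bilinear F1(rd_low), F2(rd_high);
  NumericMatrix out(nq, 4);

  // coarse seed lattice (at most 24 nodes per axis)
  const int stride_a = std::max(1, na / 24), stride_s = std::max(1, ns / 24);

  for (int q = 0; q < nq; ++q) {
    double t1 = rd1[q], t2 = rd2[q];
    if (!std::isfinite(t1) || !std::isfinite(t2)) {
      out(q, 0) = NA_REAL; out(q, 1) = NA_REAL; out(q, 2) = NA_REAL; out(q, 3) = 0;
      continue;
    }
    // seed search
    double best = R_PosInf; double u = 0, v = 0;
    for (int i = 0; i < na; i += stride_a) {
      for (int j = 0; j < ns; j += stride_s) {
        double d1 = rd_low(i, j) - t1, d2 = rd_high(i, j) - t2;
        double d = d1 * d1 + d2 * d2;
        if (d < best) { best = d; u = i; v = j; }
      }
    }
    // damped Newton on the bilinear forward map, clamped to the grid
    double r1 = F1.value(u, v) - t1, r2 = F2.value(u, v) - t2;
    for (int it = 0; it < 80; ++it) {
      double a = F1.du(u, v), b = F1.dv(u, v);
      double c = F2.du(u, v), d = F2.dv(u, v);
      double det = a * d - b * c;
      if (std::fabs(det) < 1e-300) break;
      double su = (d * r1 - b * r2) / det;
      double sv = (-c * r1 + a * r2) / det;
      // limit step to 2 cells for stability far from the solution
      double mag = std::max(std::fabs(su), std::fabs(sv));
      if (mag > 2.0) { su *= 2.0 / mag; sv *= 2.0 / mag; }
      double step = 1.0;
      double n0 = r1 * r1 + r2 * r2;
      double un = u, vn = v, r1n = r1, r2n = r2;
      for (int h = 0; h < 6; ++h) {
        un = u - step * su; vn = v - step * sv;
        if (un < 0) un = 0; if (un > na - 1) un = na - 1;
        if (vn < 0) vn = 0; if (vn > ns - 1) vn = ns - 1;
        r1n = F1.value(un, vn) - t1; r2n = F2.value(un, vn) - t2;
        if (r1n * r1n + r2n * r2n <= n0) break;
        step *= 0.5;
      }
      double moved = std::fabs(un - u) + std::fabs(vn - v);
      u = un; v = vn; r1 = r1n; r2 = r2n;
      if (r1 * r1 + r2 * r2 < 1e-28 || moved < 1e-13) break;
    }
    double resid = std::sqrt(r1 * r1 + r2 * r2);
    double scale = std::max(std::sqrt(t1 * t1 + t2 * t2), 1e-12);
    bool ok = std::isfinite(resid) && (resid / scale) <= rel_tol;
    out(q, 0) = interp_axis(mu_a_grid, u);
    out(q, 1) = interp_axis(mu_s_grid, v);
    out(q, 2) = resid;
    out(q, 3) = ok ? 1.0 : 0.0;
  }
  return out;
}
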