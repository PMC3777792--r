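#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Streamline propagation core. The direction field is the FA-weighted
// principal eigenvector, interpolated trilinearly with per-corner sign
// alignment to the current heading (eigenvectors have arbitrary sign).
// Coordinates: voxel (0,0,0) center at `org` mm, centers spaced by
// `vs`; continuous voxel coordinate u = (x - org) / vs.

namespace {

struct Grid {
  int nx, ny, nz;
  double vsx, vsy, vsz;
  double ox, oy, oz;
};

// trilinear sample of FA and of the sign-aligned weighted eigenvector
// field; returns false when the point is outside the voxel-center hull
bool sample(const Grid &g, const double *fa, const double *e1,
            const double x[3], const double h[3],
            double dir[3], double &fa_out) {
  double u[3] = {(x[0] - g.ox) / g.vsx,
                 (x[1] - g.oy) / g.vsy,
                 (x[2] - g.oz) / g.vsz};
  int dims[3] = {g.nx, g.ny, g.nz};
  int i0[3];
  double f[3];
  for (int d = 0; d < 3; ++d) {
    if (dims[d] == 1) { i0[d] = 0; f[d] = 0.0; continue; }
    if (u[d] < 0.0 || u[d] > dims[d] - 1) return false;
    double fl = std::floor(u[d]);
    i0[d] = (int)fl;
    if (i0[d] > dims[d] - 2) i0[d] = dims[d] - 2;
    f[d] = u[d] - i0[d];
  }
  fa_out = 0.0;
  dir[0] = dir[1] = dir[2] = 0.0;
  long nvox = (long)g.nx * g.ny * g.nz;
  for (int cz = 0; cz < 2; ++cz)
    for (int cy = 0; cy < 2; ++cy)
      for (int cx = 0; cx < 2; ++cx) {
        double w = (cx ? f[0] : 1 - f[0]) * (cy ? f[1] : 1 - f[1]) *
                   (cz ? f[2] : 1 - f[2]);
        if (w == 0.0) continue;
        int ii = std::min(i0[0] + cx, g.nx - 1);
        int jj = std::min(i0[1] + cy, g.ny - 1);
        int kk = std::min(i0[2] + cz, g.nz - 1);
        long lin = ii + (long)jj * g.nx + (long)kk * g.nx * g.ny;
        double fav = fa[lin];
        fa_out += w * fav;
        double ex = e1[lin], ey = e1[lin + nvox], ez = e1[lin + 2 * nvox];
        double s = (ex * h[0] + ey * h[1] + ez * h[2] >= 0.0) ? 1.0 : -1.0;
        double wf = w * fav * s;
        dir[0] += wf * ex;
        dir[1] += wf * ey;
        dir[2] += wf * ez;
      }
  return true;
}

bool unit(double v[3]) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (n < 1e-12) return false;
  v[0] /= n; v[1] /= n; v[2] /= n;
  return true;
}

} // namespace

// Propagate one half-track from `seed` with initial heading `h0`.
// Returns the point list (seed first) and a termination reason code:
// 1 low-FA (or degenerate field), 2 angle, 3 out-of-bounds,
// 4 max-length.
// [[Rcpp::export]]
List cpp_track_half(NumericVector seed, NumericVector h0,
                    NumericVector fa, NumericMatrix e1,
                    IntegerVector dims, NumericVector vs,
                    NumericVector org, double step, double max_angle,
                    double fa_stop, double max_length) {
  Grid g = {dims[0], dims[1], dims[2], vs[0], vs[1], vs[2],
            org[0], org[1], org[2]};
  const double *fap = fa.begin();
  const double *e1p = e1.begin();
  double x[3] = {seed[0], seed[1], seed[2]};
  double h[3] = {h0[0], h0[1], h0[2]};
  unit(h);
  double cos_max = std::cos(max_angle * M_PI / 180.0);
  double vox_mm = std::min(vs[0], std::min(vs[1], vs[2]));
  int lookback = std::max(1, (int)std::lround(vox_mm / step));
  std::vector<double> pts;
  pts.insert(pts.end(), x, x + 3);
  std::vector<double> hist; // heading ring, 3 per entry
  int reason = 1;
  double len = 0.0;
  long max_steps = (long)(max_length / step) + 2;
  for (long it = 0; it < max_steps; ++it) {
    double dir[3], fav;
    if (!sample(g, fap, e1p, x, h, dir, fav)) { reason = 3; break; }
    if (fav < fa_stop) { reason = 1; break; }
    // RK4 with unit-normalised stage directions
    double k1[3] = {dir[0], dir[1], dir[2]};
    if (!unit(k1)) { reason = 1; break; }
    double xm[3], k2[3], k3[3], k4[3], fdum;
    for (int d = 0; d < 3; ++d) xm[d] = x[d] + 0.5 * step * k1[d];
    if (!sample(g, fap, e1p, xm, h, k2, fdum) || !unit(k2)) {
      reason = 3; break;
    }
    for (int d = 0; d < 3; ++d) xm[d] = x[d] + 0.5 * step * k2[d];
    if (!sample(g, fap, e1p, xm, h, k3, fdum) || !unit(k3)) {
      reason = 3; break;
    }
    for (int d = 0; d < 3; ++d) xm[d] = x[d] + step * k3[d];
    if (!sample(g, fap, e1p, xm, h, k4, fdum) || !unit(k4)) {
      reason = 3; break;
    }
    double v[3];
    for (int d = 0; d < 3; ++d)
      v[d] = k1[d] + 2.0 * k2[d] + 2.0 * k3[d] + k4[d];
    if (!unit(v)) { reason = 1; break; }
    // curvature: per-step and one-voxel look-back
    if (v[0] * h[0] + v[1] * h[1] + v[2] * h[2] < cos_max) {
      reason = 2; break;
    }
    if ((long)hist.size() >= 3L * lookback) {
      size_t base = hist.size() - 3L * lookback;
      double dot = v[0] * hist[base] + v[1] * hist[base + 1] +
                   v[2] * hist[base + 2];
      if (dot < cos_max) { reason = 2; break; }
    }
    if (len + step > max_length + 1e-9) { reason = 4; break; }
    double xn[3] = {x[0] + step * v[0], x[1] + step * v[1],
                    x[2] + step * v[2]};
    bool inside = true;
    double u;
    u = (xn[0] - g.ox) / g.vsx; if (g.nx > 1 && (u < 0 || u > g.nx - 1)) inside = false;
    u = (xn[1] - g.oy) / g.vsy; if (g.ny > 1 && (u < 0 || u > g.ny - 1)) inside = false;
    u = (xn[2] - g.oz) / g.vsz; if (g.nz > 1 && (u < 0 || u > g.nz - 1)) inside = false;
    if (!inside) { reason = 3; break; }
    x[0] = xn[0]; x[1] = xn[1]; x[2] = xn[2];
    h[0] = v[0]; h[1] = v[1]; h[2] = v[2];
    hist.insert(hist.end(), v, v + 3);
    if ((long)hist.size() > 3L * (lookback + 1))
      hist.erase(hist.begin(), hist.begin() + 3);
    pts.insert(pts.end(), x, x + 3);
    len += step;
  }
  int n = pts.size() / 3;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = pts[3 * i + d];
  return List::create(_["points"] = out, _["reason"] = reason);
}
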