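#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Siddon-style per-pixel traversal lengths of straight ray segments through a
// regular 2D grid. Coordinates: lateral position x in
// [x_min, x_min + n_lat*px_lat], axial position z in [z_min, z_min + n_ax*px_ax].
// Pixel (i_ax, i_lat) is 0-based; linear index (0-based) = i_ax + n_ax*i_lat,
// i.e. matrices are stored axial-major (column-major with axial rows).
//
// Each ray runs from (x0[r], z0[r]) to (x1[r], z1[r]); the segment is clipped
// to the grid bounding box (rays leaving the field of view are truncated).
// Returns triplets (ray index, pixel index, length), all 1-based for R.
// [[Rcpp::export]]
List trace_rays(const NumericVector& x0, const NumericVector& z0,
                const NumericVector& x1, const NumericVector& z1,
                int n_ax, int n_lat, double px_ax, double px_lat,
                double x_min, double z_min) {
  const int nr = x0.size();
  const double x_max = x_min + n_lat * px_lat;
  const double z_max = z_min + n_ax * px_ax;
  std::vector<int> ri, ci;
  std::vector<double> len;
  ri.reserve(nr * 8); ci.reserve(nr * 8); len.reserve(nr * 8);

  for (int r = 0; r < nr; ++r) {
    const double dx = x1[r] - x0[r], dz = z1[r] - z0[r];
    const double L = std::sqrt(dx * dx + dz * dz);
    if (L <= 0.0) continue;

    // Liang-Barsky clip of t in [0,1] to the box.
    double t0 = 0.0, t1 = 1.0;
    bool ok = true;
    const double pv[4] = {-dx, dx, -dz, dz};
    const double qv[4] = {x0[r] - x_min, x_max - x0[r], z0[r] - z_min, z_max - z0[r]};
    for (int e = 0; e < 4 && ok; ++e) {
      if (pv[e] == 0.0) {
        if (qv[e] < 0.0) ok = false;
      } else {
        const double tt = qv[e] / pv[e];
        if (pv[e] < 0.0) { if (tt > t0) t0 = tt; }
        else             { if (tt < t1) t1 = tt; }
      }
    }
    if (!ok || t0 >= t1) continue;

    const double teps = 1e-12;
    double t = t0;
    while (t < t1 - teps) {
      // next crossing of a lateral gridline
      double tx = t1;
      if (dx != 0.0) {
        const double xc = x0[r] + t * dx;
        double idx = (xc - x_min) / px_lat;
        double nb = (dx > 0.0) ? std::floor(idx + 1e-9) + 1.0 : std::ceil(idx - 1e-9) - 1.0;
        double tt = (x_min + nb * px_lat - x0[r]) / dx;
        while (tt <= t + teps) { nb += (dx > 0.0) ? 1.0 : -1.0; tt = (x_min + nb * px_lat - x0[r]) / dx; }
        tx = tt;
      }
      // next crossing of an axial gridline
      double tz = t1;
      if (dz != 0.0) {
        const double zc = z0[r] + t * dz;
        double idx = (zc - z_min) / px_ax;
        double nb = (dz > 0.0) ? std::floor(idx + 1e-9) + 1.0 : std::ceil(idx - 1e-9) - 1.0;
        double tt = (z_min + nb * px_ax - z0[r]) / dz;
        while (tt <= t + teps) { nb += (dz > 0.0) ? 1.0 : -1.0; tt = (z_min + nb * px_ax - z0[r]) / dz; }
        tz = tt;
      }
      double tn = std::min(t1, std::min(tx, tz));
      if (tn <= t + teps) break;  // numerical safety
      const double tm = 0.5 * (t + tn);
      int i_lat = (int)std::floor((x0[r] + tm * dx - x_min) / px_lat);
      int i_ax  = (int)std::floor((z0[r] + tm * dz - z_min) / px_ax);
      if (i_lat < 0) i_lat = 0; if (i_lat >= n_lat) i_lat = n_lat - 1;
      if (i_ax < 0)  i_ax = 0;  if (i_ax >= n_ax)  i_ax = n_ax - 1;
      ri.push_back(r + 1);
      ci.push_back(i_ax + n_ax * i_lat + 1);
      len.push_back((tn - t) * L);
      t = tn;
    }
  }
  return List::create(_["ray"] = wrap(ri), _["pixel"] = wrap(ci), _["length"] = wrap(len));
}
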