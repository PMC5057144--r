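#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of a matrix at fractional (0-based) coordinates; zero outside.
static inline double bilin(const NumericMatrix& img, double x, double y) {
  const int nx = img.nrow(), ny = img.ncol();
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const double fx = x - x0, fy = y - y0;
  double v = 0.0;
  for (int dx = 0; dx <= 1; ++dx) {
    const int xi = x0 + dx;
    if (xi < 0 || xi >= nx) continue;
    const double wx = dx ? fx : 1.0 - fx;
    for (int dy = 0; dy <= 1; ++dy) {
      const int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      v += wx * (dy ? fy : 1.0 - fy) * img(xi, yi);
    }
  }
  return v;
}

// Parallel-beam forward projection of one slice.
// Ray at angle theta: position = center + t * (cos, sin) + s * (-sin, cos),
// t the detector coordinate, s the integration variable (both in pixel units).
// Returns ndet x nangle sinogram of sums * step (dimensionless, pixel-length units).
// [[Rcpp::export]]
NumericMatrix radon_forward_cpp(const NumericMatrix& slice,
                                const NumericVector& angles_rad,
                                const int ndet, const double step,
                                const double center_offset) {
  const int nx = slice.nrow(), ny = slice.ncol(), na = angles_rad.size();
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double L = std::sqrt((double)nx * nx + (double)ny * ny) + 2.0;
  const int nsteps = (int)std::ceil(L / step) + 1;
  const double s0 = -0.5 * (nsteps - 1) * step;
  NumericMatrix out(ndet, na);
  for (int a = 0; a < na; ++a) {
    const double co = std::cos(angles_rad[a]), si = std::sin(angles_rad[a]);
    for (int d = 0; d < ndet; ++d) {
      const double t = (d - (ndet - 1) / 2.0) - center_offset;
      const double bx = cx + t * co, by = cy + t * si;
      double acc = 0.0;
      for (int k = 0; k < nsteps; ++k) {
        const double s = s0 + k * step;
        acc += bilin(slice, bx - s * si, by + s * co);
      }
      out(d, a) = acc * step;
    }
  }
  return out;
}

// Backprojection of a filtered sinogram (ndet x nangle) onto an nx x ny grid.
// Linear interpolation along the detector axis; accumulates over angles.
// [[Rcpp::export]]
NumericMatrix backproject_cpp(const NumericMatrix& filt,
                              const NumericVector& angles_rad,
                              const int nx, const int ny,
                              const double center_offset) {
  const int ndet = filt.nrow(), na = filt.ncol();
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double dmid = (ndet - 1) / 2.0 + center_offset;
  NumericMatrix out(nx, ny);
  for (int a = 0; a < na; ++a) {
    const double co = std::cos(angles_rad[a]), si = std::sin(angles_rad[a]);
    for (int j = 0; j < ny; ++j) {
      const double tj = (j - cy) * si + dmid;
      for (int i = 0; i < nx; ++i) {
        const double t = (i - cx) * co + tj;
        const int t0 = (int)std::floor(t);
        if (t0 < 0 || t0 >= ndet - 1) continue;
        const double f = t - t0;
        out(i, j) += (1.0 - f) * filt(t0, a) + f * filt(t0 + 1, a);
      }
    }
  }
  return out;
}

// For each row of p (n x 3), the minimum Euclidean distance to the rows of q
// (m x 3) and the (1-based) index of the nearest row.
// [[Rcpp::export]]
List min_dist_to_points_cpp(const NumericMatrix& p, const NumericMatrix& q) {
  const int n = p.nrow(), m = q.nrow();
  NumericVector dist(n);
  IntegerVector which(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    const double px = p(i, 0), py = p(i, 1), pz = p(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = px - q(j, 0), dy = py - q(j, 1), dz = pz - q(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    dist[i] = std::sqrt(best);
    which[i] = bj + 1;
  }
  return List::create(_["dist"] = dist, _["which"] = which);
}
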