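#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Diffuse point-source kernel summed over window patches, at arbitrary points.
// [[Rcpp::export]]
NumericVector fluence_points_kernel(NumericMatrix points, NumericMatrix centers,
                                    NumericVector areas, double D,
                                    double muEff, double guard) {
  const int n = points.nrow(), P = centers.nrow();
  const double k = 1.0 / (4.0 * M_PI * D);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    for (int p = 0; p < P; ++p) {
      const double dx = x - centers(p, 0), dy = y - centers(p, 1),
                   dz = z - centers(p, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < guard) d = guard;
      acc += areas[p] * k * std::exp(-muEff * d) / d;
    }
    out[i] = acc;
  }
  return out;
}

// Same kernel over a regular voxel grid (x fastest, R column-major order).
// [[Rcpp::export]]
NumericVector fluence_grid_kernel(NumericVector origin, double spacing,
                                  IntegerVector dim, NumericMatrix centers,
                                  NumericVector areas, double D,
                                  double muEff, double guard) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], P = centers.nrow();
  const double k = 1.0 / (4.0 * M_PI * D);
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  for (int p = 0; p < P; ++p) {
    const double cx = centers(p, 0), cy = centers(p, 1), cz = centers(p, 2);
    const double ak = areas[p] * k;
    R_xlen_t idx = 0;
    for (int iz = 0; iz < nz; ++iz) {
      const double dz = origin[2] + iz * spacing - cz, dz2 = dz * dz;
      for (int iy = 0; iy < ny; ++iy) {
        const double dy = origin[1] + iy * spacing - cy, r2 = dy * dy + dz2;
        for (int ix = 0; ix < nx; ++ix) {
          const double dx = origin[0] + ix * spacing - cx;
          double d = std::sqrt(dx * dx + r2);
          if (d < guard) d = guard;
          out[idx++] += ak * std::exp(-muEff * d) / d;
        }
      }
    }
  }
  return out;
}

// Band-limited source wavelet: first derivative of a Gaussian, the N-shaped
// (bipolar) wave a point absorber radiates.  Unit peak magnitude; the
// spectral peak sits at the centre frequency fc (sigma = 1/(2 pi fc)).
// The ramp-filtered back-projection term p - t dp/dt then peaks exactly at
// the geometric delay.
static inline double dgauss(double t, double fc) {
  const double s = 1.0 / (2.0 * M_PI * fc);
  const double u = t / s;
  return -u * std::exp(0.5 - 0.5 * u * u);
}

// Forward acoustic model: point sources -> RF channel matrix for one pose.
// Amplitude per source/element: amp * S0(thetaL, thetaE) / d, arrival at
// d / vs, wavelet laid down with its continuous shape (sub-sample delays are
// exact).  sigmaL/sigmaE in radians; sigmaL <= 0 disables directivity.
// [[Rcpp::export]]
NumericMatrix forward_rf_kernel(NumericMatrix srcPos, NumericVector srcAmp,
                                NumericMatrix elemPos, NumericMatrix elemNorm,
                                NumericMatrix elemLat, int nSamples,
                                double fs, double vs_cm, double fc,
                                double sigmaL, double sigmaE) {
  const int S = srcPos.nrow(), E = elemPos.nrow();
  NumericMatrix out(E, nSamples);
  const double halfSupport = 1.6 / fc;           // seconds; wavelet tail < 1e-10
  const bool useDir = sigmaL > 0.0;
  for (int e = 0; e < E; ++e) {
    const double ex = elemPos(e, 0), ey = elemPos(e, 1), ez = elemPos(e, 2);
    const double nx = elemNorm(e, 0), ny = elemNorm(e, 1), nz = elemNorm(e, 2);
    const double lx = elemLat(e, 0), ly = elemLat(e, 1), lz = elemLat(e, 2);
    const double vx = ny * lz - nz * ly, vy = nz * lx - nx * lz,
                 vz = nx * ly - ny * lx;          // elevational axis
    for (int s = 0; s < S; ++s) {
      const double dx = srcPos(s, 0) - ex, dy = srcPos(s, 1) - ey,
                   dz = srcPos(s, 2) - ez;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d <= 0) continue;
      double w = srcAmp[s] / d;
      if (useDir) {
        const double a = (dx * nx + dy * ny + dz * nz) / d;
        const double l = (dx * lx + dy * ly + dz * lz) / d;
        const double el = (dx * vx + dy * vy + dz * vz) / d;
        const double thL = std::atan2(l, a), thE = std::atan2(el, a);
        w *= std::exp(-0.5 * thL * thL / (sigmaL * sigmaL)
                      - 0.5 * thE * thE / (sigmaE * sigmaE));
      }
      const double tau = d / vs_cm;               // arrival time, s
      const int k0 = std::max(0, (int)std::ceil((tau - halfSupport) * fs));
      const int k1 = std::min(nSamples - 1,
                              (int)std::floor((tau + halfSupport) * fs));
      for (int k = k0; k <= k1; ++k)
        out(e, k) += w * dgauss(k / fs - tau, fc);
    }
  }
  return out;
}

// Universal back-projection of one ramp-filtered plane.
// B: elements x samples matrix of p - t dp/dt (t = 0 at the first sample).
// Per voxel: weighted mean over elements of B interpolated at t = d / vs,
// weights = solid angle (area cos(gamma) / d^2, clipped at 0) times optional
// separable Gaussian directivity.  The element loop is outermost so the
// element's sample vector stays cache-resident while the per-voxel
// numerator/denominator accumulators stream sequentially.
// [[Rcpp::export]]
List backproject_kernel(NumericMatrix B, NumericMatrix elemPos,
                        NumericMatrix elemNorm, NumericMatrix elemLat,
                        double elemArea, NumericVector origin, double spacing,
                        IntegerVector dim, double fs, double vs_cm,
                        double sigmaL, double sigmaE, bool nearest) {
  const int E = elemPos.nrow(), ns = B.ncol();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  const bool useDir = sigmaL > 0.0;
  const double invSL2 = useDir ? 0.5 / (sigmaL * sigmaL) : 0.0;
  const double invSE2 = useDir ? 0.5 / (sigmaE * sigmaE) : 0.0;
  const double toSample = fs / vs_cm;
  std::vector<double> num(nvox, 0.0), den(nvox, 0.0), col(ns);
  for (int e = 0; e < E; ++e) {
    for (int k = 0; k < ns; ++k) col[k] = B(e, k);
    const double ex = elemPos(e, 0), ey = elemPos(e, 1), ez = elemPos(e, 2);
    const double nxx = elemNorm(e, 0), nyy = elemNorm(e, 1),
                 nzz = elemNorm(e, 2);
    const double lx = elemLat(e, 0), ly = elemLat(e, 1), lz = elemLat(e, 2);
    const double vx = nyy * lz - nzz * ly, vy = nzz * lx - nxx * lz,
                 vz = nxx * ly - nyy * lx;        // elevational axis
    R_xlen_t idx = 0;
    for (int iz = 0; iz < nz; ++iz) {
      const double dz = origin[2] + iz * spacing - ez;
      for (int iy = 0; iy < ny; ++iy) {
        const double dy = origin[1] + iy * spacing - ey;
        const double dyz2 = dy * dy + dz * dz;
        for (int ix = 0; ix < nx; ++ix, ++idx) {
          const double dx = origin[0] + ix * spacing - ex;
          const double d2 = dx * dx + dyz2;
          const double d = std::sqrt(d2);
          if (d <= 0) continue;
          const double a = (dx * nxx + dy * nyy + dz * nzz) / d;
          if (a <= 0) continue;                   // back-facing: weight 0
          double w = elemArea * a / d2;
          if (useDir) {
            const double l = (dx * lx + dy * ly + dz * lz) / d;
            const double el = (dx * vx + dy * vy + dz * vz) / d;
            const double thL = std::atan2(l, a), thE = std::atan2(el, a);
            w *= std::exp(-thL * thL * invSL2 - thE * thE * invSE2);
          }
          const double ts = d * toSample;         // fractional sample (0-based)
          double val;
          if (nearest) {
            const int k = (int)std::lround(ts);
            if (k < 0 || k > ns - 1) continue;
            val = col[k];
          } else {
            const int k = (int)std::floor(ts);
            if (k < 0 || k > ns - 2) continue;
            const double f = ts - k;
            val = col[k] * (1.0 - f) + col[k + 1] * f;
          }
          num[idx] += w * val;
          den[idx] += w;
        }
      }
    }
  }
  NumericVector out(nvox);
  R_xlen_t uncovered = 0;
  for (R_xlen_t i = 0; i < nvox; ++i) {
    if (den[i] > 0.0) out[i] = num[i] / den[i];
    else { out[i] = 0.0; ++uncovered; }
  }
  return List::create(_["values"] = out,
                      _["uncovered"] = (double)uncovered);
}
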