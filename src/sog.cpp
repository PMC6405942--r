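#include <Rcpp.h>
using namespace Rcpp;

// Sum-of-Gaussians chain evaluation over a pixel grid, together with the
// per-pixel accumulators needed for the analytic gradient of the filament
// models.  Gaussians use the normal form exp(-dx^2/(2 sx^2) - dy^2/(2 sy^2)).
//
// Inputs per Gaussian g of the chain: centre (mux, muy), derivative weight
// jidx (0 for the terminal Gaussians, the chain index j for interior ones)
// and direction fields (bx,by) for the spacing derivative, (jx,jy) for the
// curvature derivative and (lx,ly) for the inflection derivative (all-zero
// vectors for the line model).
//
// Returns an n x 6 matrix with columns
//   1: sum_g G_g                 (model without amplitude/background)
//   2: G_first                   (start Gaussian)
//   3: G_last                    (end Gaussian)
//   4: sum_g jidx_g ((px-mux_g) bx_g / sx^2 + (py-muy_g) by_g / sy^2) G_g
//   5: same with (jx, jy)
//   6: same with (lx, ly)

// [[Rcpp::export(name = ".sog_fields_cpp")]]
NumericMatrix sog_fields_cpp(NumericVector px, NumericVector py,
                             NumericVector mux, NumericVector muy,
                             NumericVector jidx,
                             NumericVector bx, NumericVector by,
                             NumericVector jx, NumericVector jy,
                             NumericVector lx, NumericVector ly,
                             double sx, double sy) {
  const int n = px.size(), ng = mux.size();
  const double isx2 = 1.0 / (2.0 * sx * sx), isy2 = 1.0 / (2.0 * sy * sy);
  const double wx = 1.0 / (sx * sx), wy = 1.0 / (sy * sy);
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    double f = 0, gs = 0, ge = 0, dds = 0, db = 0, di = 0;
    const double x = px[i], y = py[i];
    for (int g = 0; g < ng; ++g) {
      const double dx = x - mux[g], dy = y - muy[g];
      const double e2 = dx * dx * isx2 + dy * dy * isy2;
      if (e2 > 30.0) continue;                   // exp(-30) ~ 1e-13: negligible
      const double G = std::exp(-e2);
      f += G;
      if (g == 0) gs = G;
      if (g == ng - 1) ge = G;
      const double j = jidx[g];
      if (j != 0.0) {
        const double ax = dx * wx, ay = dy * wy;
        dds += j * (ax * bx[g] + ay * by[g]) * G;
        db  += j * (ax * jx[g] + ay * jy[g]) * G;
        di  += j * (ax * lx[g] + ay * ly[g]) * G;
      }
    }
    out(i, 0) = f; out(i, 1) = gs; out(i, 2) = ge;
    out(i, 3) = dds; out(i, 4) = db; out(i, 5) = di;
  }
  return out;
}

// Plain chain render: adds A * sum_g G_g to an image region given pixel
// coordinates; used by the simulator where only intensities are needed.
// [[Rcpp::export(name = ".sog_render_cpp")]]
NumericVector sog_render_cpp(NumericVector px, NumericVector py,
                             NumericVector mux, NumericVector muy,
                             double amp, double sx, double sy) {
  const int n = px.size(), ng = mux.size();
  const double isx2 = 1.0 / (2.0 * sx * sx), isy2 = 1.0 / (2.0 * sy * sy);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = 0;
    const double x = px[i], y = py[i];
    for (int g = 0; g < ng; ++g) {
      const double dx = x - mux[g], dy = y - muy[g];
      const double e2 = dx * dx * isx2 + dy * dy * isy2;
      if (e2 > 30.0) continue;
      f += std::exp(-e2);
    }
    out[i] = amp * f;
  }
  return out;
}
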