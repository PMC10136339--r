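#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Surface potential of propagating intracellular current sources.
//
// Each fiber carries two mirrored triplets of point current sources (a
// tripole per propagation direction) that start collapsed at the innervation
// zone, travel along +z / -z at the conduction velocity, and collapse again
// at the fiber end: because the three pole amplitudes sum to zero, the
// potential vanishes exactly before generation and after extinction.
//
// The potential of one pole at the skin-plane electrode (ex, 0, ez) is
//   P / sqrt(Ka * ((ex - fx)^2 + y^2) + (ez - zp)^2) / (2 * pi * sigma_x)
// with Ka = sigma_z / sigma_x the conductivity anisotropy ratio. Distances
// are in mm; the overall amplitude scale is arbitrary.
//
// fib_tilt lets a fiber run at a shallow angle to the skin: its depth at
// axial position z is y + tilt * (z - iz). Depth is floored at y_min so a
// tilted fiber never pierces the skin plane.

// [[Rcpp::export]]
NumericMatrix muap_template_cpp(NumericVector fib_x, NumericVector fib_y,
                                NumericVector fib_tilt,
                                NumericVector elec_x, NumericVector elec_z,
                                NumericVector pole_amp,
                                NumericVector pole_offset,
                                double iz_z, double half_length,
                                double velocity, double ka, double sigma_x,
                                double fs, int n_samples, double y_min) {
  const int nf = fib_x.size(), ne = elec_x.size(), np = pole_amp.size();
  NumericMatrix out(n_samples, ne);
  const double scale = 1.0 / (2.0 * M_PI * sigma_x);

  for (int s = 0; s < n_samples; ++s) {
    const double t = s / fs;
    // pole axial positions at time t, both directions
    for (int d = 0; d < 2; ++d) {
      const double dir = d == 0 ? 1.0 : -1.0;
      for (int k = 0; k < np; ++k) {
        double travel = velocity * t - pole_offset[k];
        if (travel < 0.0) travel = 0.0;
        if (travel > half_length) travel = half_length;
        const double zp = iz_z + dir * travel;
        const double amp = pole_amp[k] * scale;
        const double *ex = elec_x.begin(), *ez = elec_z.begin();
        double *row = &out(s, 0);
        const int stride = n_samples;
        for (int f = 0; f < nf; ++f) {
          double yp = fib_y[f] + fib_tilt[f] * (zp - iz_z);
          if (yp < y_min) yp = y_min;
          const double trans = fib_x[f];
          const double kay2 = ka * yp * yp;
          for (int e = 0; e < ne; ++e) {
            const double dx = ex[e] - trans;
            const double dz = ez[e] - zp;
            const double r2 = ka * dx * dx + kay2 + dz * dz;
            row[e * stride] += amp / std::sqrt(r2);
          }
        }
      }
    }
  }
  return out;
}

// Adds amp * template rows into a recording at given sample offsets
// (sparse spike-train / template superposition).
// [[Rcpp::export]]
void add_template_cpp(NumericMatrix rec, NumericMatrix tmpl,
                      IntegerVector at, NumericVector amp) {
  const int n = rec.nrow(), nk = tmpl.nrow(), nc = rec.ncol();
  for (int j = 0; j < at.size(); ++j) {
    const int i0 = at[j] - 1;           // R is 1-based
    if (i0 >= n) continue;
    const int len = std::min(nk, n - i0);
    const double a = amp[j];
    for (int c = 0; c < nc; ++c) {
      double *rc = &rec(i0, c);
      const double *tc = &tmpl(0, c);
      for (int i = 0; i < len; ++i) rc[i] += a * tc[i];
    }
  }
}
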