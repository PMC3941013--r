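#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin dynamics of a single ion in a 1-D free-energy
// profile W(z), dragged by a harmonic trap moving at constant velocity.
//
//   z <- z + (D/kBT) * (F_pmf + k*(z_trap - z)) * dt + sqrt(2*D*dt) * xi
//
// with xi ~ N(0,1) drawn from R's RNG (so set.seed() governs the run).
// The deterministic mobility D/kBT is the Einstein relation; disabling
// `noise` gives the zero-temperature drift limit while keeping the drift.
//
// kind: 0 = flat, 1 = linear (par[0] = slope kJ/mol/nm),
//       2 = gaussian barrier (par[0] = height, par[1] = center, par[2] = width),
//       3 = tabulated (tab_z ascending, tab_dW = dW/dz, linear interpolation,
//           clamped at the ends).
//
// Returns a matrix with one row per recorded sample (every `stride` steps,
// always including step 0 and the final step): t, z_trap, z_ion, F_spring.

static inline double grad_w(const double z, const int kind,
                            const NumericVector& par,
                            const NumericVector& tab_z,
                            const NumericVector& tab_dW) {
  switch (kind) {
  case 0:
    return 0.0;
  case 1:
    return par[0];
  case 2: {
    const double dz = z - par[1];
    const double w2 = par[2] * par[2];
    return -par[0] * dz / w2 * std::exp(-0.5 * dz * dz / w2);
  }
  default: {
    const int n = tab_z.size();
    if (z <= tab_z[0]) return tab_dW[0];
    if (z >= tab_z[n - 1]) return tab_dW[n - 1];
    // binary search for the bracketing interval
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      const int mid = (lo + hi) / 2;
      if (tab_z[mid] <= z) lo = mid; else hi = mid;
    }
    const double f = (z - tab_z[lo]) / (tab_z[hi] - tab_z[lo]);
    return tab_dW[lo] + f * (tab_dW[hi] - tab_dW[lo]);
  }
  }
}

// [[Rcpp::export]]
NumericMatrix langevin_steer_cpp(double z0, double z_min, double z_max,
                                 double k, double v, double dt, double D,
                                 double kBT, bool noise, double t_max,
                                 int kind, NumericVector par,
                                 NumericVector tab_z, NumericVector tab_dW,
                                 int stride) {
  const double span_time = (v > 0.0) ? (z_max - z_min) / v : t_max;
  const long n_steps = (long)std::ceil(span_time / dt);
  const long n_rec = n_steps / stride + 2;
  NumericMatrix out(n_rec, 4);
  const double mob = D / kBT;
  const double sig = noise ? std::sqrt(2.0 * D * dt) : 0.0;

  double z = z0;
  long irec = 0;
  RNGScope scope;
  for (long i = 0; i <= n_steps; ++i) {
    const double t = i * dt;
    const double z_trap = z_min + v * t;
    if (i % stride == 0 || i == n_steps) {
      out(irec, 0) = t;
      out(irec, 1) = z_trap;
      out(irec, 2) = z;
      out(irec, 3) = k * (z_trap - z);
      ++irec;
    }
    if (i == n_steps) break;
    const double f_tot = -grad_w(z, kind, par, tab_z, tab_dW)
      + k * (z_trap - z);
    z += mob * f_tot * dt + (noise ? sig * norm_rand() : 0.0);
    if (!std::isfinite(z))
      stop("Langevin trajectory diverged (non-finite position at step %ld)", i);
  }
  return out(Range(0, irec - 1), _);
}
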