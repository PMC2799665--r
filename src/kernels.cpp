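#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Lagged product averages for the second-order autocorrelation.
// For each integer lag k returns mean over valid t of x[t] * x[t+k]
// together with the number of complete (t, t+k) pairs. Only pairs fully
// inside the record are used (no periodic wrap).
// [[Rcpp::export]]
List autocorr_lags_cpp(NumericVector x, IntegerVector lags) {
  const R_xlen_t n = x.size();
  const int m = lags.size();
  NumericVector num(m);
  IntegerVector npairs(m);
  for (int j = 0; j < m; ++j) {
    const R_xlen_t k = lags[j];
    if (k < 0 || k >= n) stop("lag %d is outside the series", (int)k);
    const R_xlen_t np = n - k;
    double s = 0.0;
    const double *p = REAL(x);
    for (R_xlen_t t = 0; t < np; ++t) s += p[t] * p[t + k];
    num[j] = s / (double)np;
    npairs[j] = (int)np;
  }
  return List::create(_["mean_product"] = num, _["n_pairs"] = npairs);
}

// Hydrogen-bond existence autocorrelation over a frames x bonds 0/1 matrix.
// intermittent: C(k) = sum_b sum_t0 h[t0,b] h[t0+k,b] / sum_b sum_t0 h[t0,b]
// continuous:   numerator counts t0 with h intact at every step in [t0, t0+k]
// The denominator runs over the same valid t0 range, so C(0) = 1 exactly.
// [[Rcpp::export]]
List hbond_corr_cpp(IntegerMatrix h, IntegerVector lags, bool continuous) {
  const int n = h.nrow(), nb = h.ncol(), m = lags.size();
  NumericVector val(m);
  IntegerVector npairs(m);
  for (int j = 0; j < m; ++j) {
    const int k = lags[j];
    if (k < 0 || k >= n) stop("lag %d is outside the series", k);
    double num = 0.0, den = 0.0;
    for (int b = 0; b < nb; ++b) {
      if (!continuous) {
        for (int t = 0; t < n - k; ++t) {
          if (h(t, b)) {
            den += 1.0;
            if (h(t + k, b)) num += 1.0;
          }
        }
      } else {
        // run-length decomposition: a run of L intact frames contributes
        // max(0, L - k) continuously-intact pairs and min(L, n-k-start...)
        int t = 0;
        while (t < n) {
          if (h(t, b)) {
            int L = 0;
            const int start = t;
            while (t < n && h(t, b)) { ++L; ++t; }
            // denominator: intact starting points with a complete (t0,t0+k)
            const int last_valid = std::min(start + L - 1, n - 1 - k);
            if (last_valid >= start) den += (double)(last_valid - start + 1);
            if (L > k) {
              const int lv2 = std::min(start + L - 1 - k, n - 1 - k);
              if (lv2 >= start) num += (double)(lv2 - start + 1);
            }
          } else ++t;
        }
      }
    }
    if (den == 0.0) stop("no intact starting frames at lag %d", k);
    val[j] = num / den;
    npairs[j] = (int)den;
  }
  return List::create(_["value"] = val, _["n_pairs"] = npairs);
}

// Overdamped (Brownian) dynamics of a bead-spring chain.
// Units: nm, ps, kJ/mol; kB = 0.0083145 kJ/mol/K. Beads carry unit mass
// (1 u) so the friction parameter gamma (1/ps) equals the friction
// coefficient zeta in u/ps and the bead diffusion constant is
// D = kB*T/zeta in nm^2/ps.
//
// Potential terms:
//   bonds:   k_bond/2 * (|r_{i+1}-r_i| - b)^2
//   bending: k_bend * (1 - cos theta) over consecutive bond pairs
//   attraction (|i-j| >= 3): -eps/2 * (1 + cos(pi r / r_attr)) for r < r_attr
//   excluded volume: k_ev/2 * (sigma - r)^2 for r < sigma, all |i-j| >= 2
//
// The rng_seed argument seeds a dedicated mt19937_64 stream (derived from
// the user's master seed on the R side).
// [[Rcpp::export]]
List langevin_chain_cpp(int n_beads, double b, double k_bond, double k_bend,
                        double eps, double r_attr, double sigma_ev,
                        double temperature, double friction, double dt,
                        double n_steps_d, int distance_stride,
                        int frame_stride, NumericMatrix x0, double rng_seed) {
  const double kB = 0.0083145;
  const double kT = kB * temperature;
  const double zeta = friction; // unit bead mass
  const double mob = dt / zeta;
  const double noise = (temperature > 0.0) ? std::sqrt(2.0 * kT * dt / zeta) : 0.0;
  const double k_ev = 5000.0; // soft-core repulsion stiffness, kJ/mol/nm^2
  const long long n_steps = (long long)n_steps_d;

  std::vector<double> X(3 * n_beads), F(3 * n_beads);
  for (int i = 0; i < n_beads; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = x0(i, d);

  const long long n_dist = n_steps / distance_stride;
  NumericVector dist(n_dist);
  const long long n_frames = frame_stride > 0 ? n_steps / frame_stride : 0;
  NumericMatrix frames(n_frames > 0 ? n_frames : 1, n_frames > 0 ? 3 * n_beads : 1);

  // dedicated generator: R's RNG is too slow for ~1e9 normal draws; the
  // integer seed is derived from the user's master seed on the R side.
  std::mt19937_64 rng((uint64_t)rng_seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  long long i_dist = 0, i_frame = 0;

  for (long long step = 1; step <= n_steps; ++step) {
    std::fill(F.begin(), F.end(), 0.0);
    // bonds
    for (int i = 0; i < n_beads - 1; ++i) {
      double dx[3], r2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        dx[d] = X[3 * (i + 1) + d] - X[3 * i + d];
        r2 += dx[d] * dx[d];
      }
      const double r = std::sqrt(r2);
      const double fmag = -k_bond * (r - b) / r; // along dx, on bead i+1
      for (int d = 0; d < 3; ++d) {
        F[3 * (i + 1) + d] += fmag * dx[d];
        F[3 * i + d] -= fmag * dx[d];
      }
    }
    // bending: U = k_bend * (1 - cos theta_i), theta between u=r_i->r_{i+1}
    if (k_bend > 0.0) {
      for (int i = 1; i < n_beads - 1; ++i) {
        double u[3], v[3], lu2 = 0, lv2 = 0, uv = 0;
        for (int d = 0; d < 3; ++d) {
          u[d] = X[3 * i + d] - X[3 * (i - 1) + d];
          v[d] = X[3 * (i + 1) + d] - X[3 * i + d];
          lu2 += u[d] * u[d]; lv2 += v[d] * v[d]; uv += u[d] * v[d];
        }
        const double lu = std::sqrt(lu2), lv = std::sqrt(lv2);
        const double c = uv / (lu * lv);
        // -dU/dx = k_bend * d(cos theta)/dx
        for (int d = 0; d < 3; ++d) {
          const double dc_da = -(v[d] / (lu * lv) - c * u[d] / lu2);
          const double dc_dc = u[d] / (lu * lv) - c * v[d] / lv2;
          const double dc_db = -dc_da - dc_dc;
          F[3 * (i - 1) + d] += k_bend * dc_da;
          F[3 * i + d]       += k_bend * dc_db;
          F[3 * (i + 1) + d] += k_bend * dc_dc;
        }
      }
    }
    // nonbonded
    if (eps > 0.0 || sigma_ev > 0.0) {
      const double rc = std::max(r_attr, sigma_ev);
      for (int i = 0; i < n_beads; ++i) {
        for (int j = i + 2; j < n_beads; ++j) {
          double dx[3], r2 = 0.0;
          for (int d = 0; d < 3; ++d) {
            dx[d] = X[3 * j + d] - X[3 * i + d];
            r2 += dx[d] * dx[d];
          }
          if (r2 > rc * rc) continue;
          const double r = std::sqrt(r2);
          double fmag = 0.0; // radial dU/dr; force on j is -(dU/dr) * dx/r
          if (eps > 0.0 && j - i >= 3 && r < r_attr) {
            fmag += eps * M_PI / (2.0 * r_attr) * std::sin(M_PI * r / r_attr);
          }
          if (sigma_ev > 0.0 && r < sigma_ev) {
            fmag += -k_ev * (sigma_ev - r);
          }
          if (fmag != 0.0 && r > 1e-12) {
            const double s = -fmag / r;
            for (int d = 0; d < 3; ++d) {
              F[3 * j + d] += s * dx[d];
              F[3 * i + d] -= s * dx[d];
            }
          }
        }
      }
    }
    // Euler-Maruyama update
    if (noise > 0.0) {
      for (int i = 0; i < 3 * n_beads; ++i)
        X[i] += mob * F[i] + noise * gauss(rng);
    } else {
      for (int i = 0; i < 3 * n_beads; ++i) X[i] += mob * F[i];
    }

    if (step % distance_stride == 0) {
      double r2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        const double dd = X[3 * (n_beads - 1) + d] - X[d];
        r2 += dd * dd;
      }
      const double r = std::sqrt(r2);
      if (!std::isfinite(r))
        stop("integration diverged (non-finite coordinates) at step %g",
             (double)step);
      dist[i_dist++] = r;
    }
    if (frame_stride > 0 && step % frame_stride == 0) {
      for (int i = 0; i < 3 * n_beads; ++i) frames(i_frame, i) = X[i];
      ++i_frame;
    }
  }

  NumericMatrix xf(n_beads, 3);
  for (int i = 0; i < n_beads; ++i)
    for (int d = 0; d < 3; ++d) xf(i, d) = X[3 * i + d];

  return List::create(_["end_to_end"] = dist, _["frames"] = frames,
                      _["n_frames"] = (double)i_frame, _["x_final"] = xf);
}

// Interior dwell times of a binary series by run-length scan.
// Returns durations (in steps) of maximal runs, their state, and a flag
// for runs truncated by the record boundary.
// [[Rcpp::export]]
List runs_cpp(IntegerVector s) {
  const R_xlen_t n = s.size();
  std::vector<int> len, st, trunc;
  R_xlen_t t = 0;
  while (t < n) {
    const int v = s[t];
    R_xlen_t t0 = t;
    while (t < n && s[t] == v) ++t;
    len.push_back((int)(t - t0));
    st.push_back(v);
    trunc.push_back((t0 == 0 || t == n) ? 1 : 0);
  }
  return List::create(_["length"] = wrap(len), _["state"] = wrap(st),
                      _["truncated"] = wrap(trunc));
}
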