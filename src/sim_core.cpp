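#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the coupled infection/degradation system:
//   dx_i/dt = alpha (1 - x_i) sum_{j != i} (w_ij / k_j) x_j
//   dw_ij/dt = -beta_ad w_ij (x_i + x_j) + drift_const_ij + 2 drift_age_ij age(t)
// x and W are updated simultaneously from the same pre-step state; x is
// clamped to [0, 1] and W at 0. Links whose weight is exactly 0 are frozen
// (degradation vanishes with w and the aging drift never creates links),
// so the integration runs over the static list of initially nonzero links
// and node strengths are maintained incrementally.
//
// freeze_strength = true evaluates k_j once from the initial matrix instead
// of from the current (decaying) matrix at every step.
//
// [[Rcpp::export]]
List sim_core_cpp(NumericMatrix W0, NumericVector x0, double alpha,
                  double beta_ad, NumericMatrix drift_const,
                  NumericMatrix drift_age, double age0, int years,
                  int steps_per_year, bool freeze_strength) {
  const int N = W0.nrow();
  const double dt = 1.0 / steps_per_year;
  const bool infect = alpha != 0.0;

  // static link list of the initial support (upper triangle)
  std::vector<int> li, lj;
  std::vector<double> w, dc, da;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (W0(i, j) > 0.0) {
        li.push_back(i);
        lj.push_back(j);
        w.push_back(W0(i, j));
        dc.push_back(drift_const(i, j));
        da.push_back(drift_age(i, j));
      }
    }
  }
  const int M = (int) w.size();

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k(N, 0.0), xs(N), acc(N);
  for (int l = 0; l < M; ++l) {
    k[li[l]] += w[l];
    k[lj[l]] += w[l];
  }

  List W_snap(years + 1), x_snap(years + 1);
  auto snapshot = [&](int slot) {
    NumericMatrix Ws(N, N);
    for (int l = 0; l < M; ++l) {
      Ws(li[l], lj[l]) = w[l];
      Ws(lj[l], li[l]) = w[l];
    }
    W_snap[slot] = Ws;
    x_snap[slot] = NumericVector(x.begin(), x.end());
  };
  snapshot(0);

  for (int y = 0; y < years; ++y) {
    for (int s = 0; s < steps_per_year; ++s) {
      const double age = age0 + y + s * dt;
      if (infect) {
        for (int j = 0; j < N; ++j) {
          xs[j] = (k[j] > 0.0) ? x[j] / k[j] : 0.0;
          acc[j] = 0.0;
        }
        for (int l = 0; l < M; ++l) {
          const double wl = w[l];
          if (wl == 0.0) continue;
          acc[li[l]] += wl * xs[lj[l]];
          acc[lj[l]] += wl * xs[li[l]];
        }
      }
      for (int l = 0; l < M; ++l) {
        const double wl = w[l];
        if (wl == 0.0) continue;
        double rate = dc[l] + 2.0 * da[l] * age;
        if (beta_ad != 0.0) rate -= beta_ad * wl * (x[li[l]] + x[lj[l]]);
        double wn = wl + dt * rate;
        if (wn < 0.0) wn = 0.0;
        if (!freeze_strength) {
          const double d = wn - wl;
          k[li[l]] += d;
          k[lj[l]] += d;
        }
        w[l] = wn;
      }
      if (infect) {
        for (int i = 0; i < N; ++i) {
          double xi = x[i] + dt * alpha * (1.0 - x[i]) * acc[i];
          if (xi < 0.0) xi = 0.0;
          if (xi > 1.0) xi = 1.0;
          x[i] = xi;
        }
      }
    }
    snapshot(y + 1);
  }
  return List::create(_["W"] = W_snap, _["x"] = x_snap);
}
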