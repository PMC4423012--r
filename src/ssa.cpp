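#include <Rcpp.h>
using namespace Rcpp;

// Shared kinetics for the crosstalk network.
//
// State layout: [ERSS, AUT, APO_1, ..., APO_n] (concentrations).  The
// unmodified apoptosis-inducer pool APO_0 = APO_T - sum(APO_i) is implicit.
// The stochastic engine uses the same rate laws evaluated at counts/Omega,
// multiplied by Omega, so that sum(stoich * propensity) / Omega recovers
// the deterministic right-hand side exactly.

struct Pars {
  double ERSS_T, AUT_T, APO_T;
  double ka_e, ki_e;
  double kaau, kaau_p, J_aa, J_ia, kiau, kiau_p;
  double kaap, kiap, kiap_p, k_fb;
  int n_steps;
  Pars(const List& p)
      : ERSS_T(p["ERSS_T"]), AUT_T(p["AUT_T"]), APO_T(p["APO_T"]),
        ka_e(p["ka_e"]), ki_e(p["ki_e"]), kaau(p["kaau"]),
        kaau_p(p["kaau_p"]), J_aa(p["J_aa"]), J_ia(p["J_ia"]),
        kiau(p["kiau"]), kiau_p(p["kiau_p"]), kaap(p["kaap"]),
        kiap(p["kiap"]), kiap_p(p["kiap_p"]), k_fb(p["k_fb"]),
        n_steps(as<int>(p["n_steps"])) {}
};

// [[Rcpp::export]]
NumericVector crosstalk_rhs_cpp(NumericVector state, double S, List params) {
  Pars pp(params);
  const int n = pp.n_steps;
  if (state.size() != 2 + n) stop("state length does not match n_steps");
  const double E = state[0], A = state[1];
  const double Pact = state[2 + n - 1];

  NumericVector d(2 + n);
  d[0] = pp.ka_e * S * (pp.ERSS_T - E) - pp.ki_e * E;

  const double va = pp.kaau + pp.kaau_p * E;
  const double vi = pp.kiau + pp.kiau_p * Pact;
  d[1] = va * (pp.AUT_T - A) / (pp.J_aa + pp.AUT_T - A)
       - vi * A / (pp.J_ia + A);

  double chain_sum = 0.0;
  for (int i = 0; i < n; ++i) chain_sum += state[2 + i];
  const double P0 = pp.APO_T - chain_sum;
  const double kf = pp.kaap * E;
  const double kb = pp.kiap / (1.0 + pp.k_fb * Pact) + pp.kiap_p * A;

  // distributive chain: P0 <-> P1 <-> ... <-> Pn
  for (int i = 0; i < n; ++i) {
    const double prev = (i == 0) ? P0 : state[2 + i - 1];
    double di = kf * prev - kb * state[2 + i];
    if (i < n - 1) di -= kf * state[2 + i] - kb * state[2 + i + 1];
    d[2 + i] = di;
  }
  return d;
}

// Propensities at integer counts x (length 2+n), stressor S, system size Om.
// Reaction order: ERSS on, ERSS off, AUT on, AUT off,
// then for each chain step i: forward(i), backward(i).
static void propensities(const Pars& pp, const std::vector<int>& x,
                         double S, double Om, int NET, int NAT, int NPT,
                         std::vector<double>& a) {
  const int n = pp.n_steps;
  const double E = x[0] / Om, A = x[1] / Om;
  const double Pact = x[2 + n - 1] / Om;
  int chain = 0;
  for (int i = 0; i < n; ++i) chain += x[2 + i];
  const int P0 = NPT - chain;

  a[0] = pp.ka_e * S * (NET - x[0]);
  a[1] = pp.ki_e * x[0];
  const double freeA = (NAT - x[1]) / Om;
  a[2] = Om * (pp.kaau + pp.kaau_p * E) * freeA / (pp.J_aa + freeA);
  a[3] = Om * (pp.kiau + pp.kiau_p * Pact) * A / (pp.J_ia + A);
  const double kf = pp.kaap * E;
  const double kb = pp.kiap / (1.0 + pp.k_fb * Pact) + pp.kiap_p * A;
  for (int i = 0; i < n; ++i) {
    const int prev = (i == 0) ? P0 : x[2 + i - 1];
    a[4 + 2 * i] = kf * prev;
    a[5 + 2 * i] = kb * x[2 + i];
  }
}

// [[Rcpp::export]]
NumericVector ssa_drift_cpp(IntegerVector counts, double S, List params,
                            double Omega) {
  // sum(stoich * propensity) / Omega at a given integer state: used by the
  // tests to assert that the reaction set matches the ODE right-hand side.
  Pars pp(params);
  const int n = pp.n_steps, ns = 2 + n, nr = 4 + 2 * n;
  const int NET = (int)std::lround(pp.ERSS_T * Omega);
  const int NAT = (int)std::lround(pp.AUT_T * Omega);
  const int NPT = (int)std::lround(pp.APO_T * Omega);
  std::vector<int> x(counts.begin(), counts.end());
  std::vector<double> a(nr);
  propensities(pp, x, S, Omega, NET, NAT, NPT, a);
  NumericVector d(ns);
  d[0] = (a[0] - a[1]) / Omega;
  d[1] = (a[2] - a[3]) / Omega;
  for (int i = 0; i < n; ++i) {
    double di = a[4 + 2 * i] - a[5 + 2 * i];
    if (i < n - 1) di -= a[4 + 2 * (i + 1)] - a[5 + 2 * (i + 1)];
    d[2 + i] = di / Omega;
  }
  return d;
}

// [[Rcpp::export]]
NumericVector ssa_propensities_cpp(IntegerVector counts, double S,
                                   List params, double Omega) {
  Pars pp(params);
  const int nr = 4 + 2 * pp.n_steps;
  const int NET = (int)std::lround(pp.ERSS_T * Omega);
  const int NAT = (int)std::lround(pp.AUT_T * Omega);
  const int NPT = (int)std::lround(pp.APO_T * Omega);
  std::vector<int> x(counts.begin(), counts.end());
  std::vector<double> a(nr);
  propensities(pp, x, S, Omega, NET, NAT, NPT, a);
  return NumericVector(a.begin(), a.end());
}

// Exact stochastic simulation (Gillespie direct method) of one cell.
//
// The stressor is piecewise constant; the next-reaction time is truncated
// at protocol segment boundaries, where propensities are re-evaluated.
// Uses R's RNG so that trajectories are reproducible under set.seed().
//
// seg_start / seg_level describe the protocol; t_out is the output grid
// (must start at 0, increasing).  x0 are initial counts.
// [[Rcpp::export]]
NumericMatrix ssa_simulate_cpp(List params, NumericVector seg_start,
                               NumericVector seg_level, double t_end,
                               NumericVector t_out, IntegerVector x0,
                               double Omega) {
  Pars pp(params);
  const int n = pp.n_steps, ns = 2 + n, nr = 4 + 2 * n;
  const int NET = (int)std::lround(pp.ERSS_T * Omega);
  const int NAT = (int)std::lround(pp.AUT_T * Omega);
  const int NPT = (int)std::lround(pp.APO_T * Omega);

  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> a(nr);
  NumericMatrix out(t_out.size(), ns);
  R_len_t iout = 0;

  int seg = 0;
  const int nseg = seg_start.size();
  double t = 0.0;
  RNGScope scope;

  while (true) {
    double S = seg_level[seg];
    double seg_end = (seg + 1 < nseg) ? seg_start[seg + 1] : t_end;

    while (t < seg_end) {
      propensities(pp, x, S, Omega, NET, NAT, NPT, a);
      double atot = 0.0;
      for (int j = 0; j < nr; ++j) atot += a[j];
      if (!R_FINITE(atot) || atot > 1e12) {
        stop("propensity overflow at t=%g (total %g)", t, atot);
      }

      double t_next;
      if (atot <= 0.0) {
        t_next = seg_end;  // frozen state until the protocol changes
      } else {
        t_next = t + R::exp_rand() / atot;
      }

      double t_fill = std::min(t_next, seg_end);
      while (iout < t_out.size() && t_out[iout] <= t_fill) {
        for (int k = 0; k < ns; ++k) out(iout, k) = x[k] / Omega;
        ++iout;
      }

      if (t_next >= seg_end) { t = seg_end; break; }
      t = t_next;

      double u = unif_rand() * atot, acc = 0.0;
      int j = nr - 1;
      for (int k = 0; k < nr; ++k) {
        acc += a[k];
        if (u <= acc) { j = k; break; }
      }
      switch (j) {
        case 0: ++x[0]; break;
        case 1: --x[0]; break;
        case 2: ++x[1]; break;
        case 3: --x[1]; break;
        default: {
          int i = (j - 4) / 2;
          if ((j - 4) % 2 == 0) {       // forward: APO_{i-1} -> APO_i
            ++x[2 + i];
            if (i > 0) --x[2 + i - 1];  // i == 0 consumes the implicit pool
          } else {                      // backward: APO_i -> APO_{i-1}
            --x[2 + i];
            if (i > 0) ++x[2 + i - 1];
          }
        }
      }
    }
    if (seg + 1 >= nseg) break;
    ++seg;
  }

  while (iout < t_out.size()) {
    for (int k = 0; k < ns; ++k) out(iout, k) = x[k] / Omega;
    ++iout;
  }
  return out;
}
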