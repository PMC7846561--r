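#include <Rcpp.h>
using namespace Rcpp;

// Transition rate at one half-grid sample. Types: 0 constant, 1
// proportional to [glu], 2 Mg block (rate * exp(-V / slope)), 3 Mg
// unblock (rate * exp(V / slope)).
static inline double rate_at(int type, double rate, double slope,
                             double glu, double volt) {
  switch (type) {
  case 0: return rate;
  case 1: return rate * glu;
  case 2: return rate * std::exp(-volt / slope);
  case 3: return rate * std::exp(volt / slope);
  }
  return 0.0;
}

static void deriv(const std::vector<double> &p, std::vector<double> &dp,
                  const IntegerVector &from, const IntegerVector &to,
                  const IntegerVector &type, const NumericVector &rate,
                  const NumericVector &slope, double glu, double volt) {
  std::fill(dp.begin(), dp.end(), 0.0);
  const int m = from.size();
  for (int e = 0; e < m; ++e) {
    double f = rate_at(type[e], rate[e], slope[e], glu, volt) * p[from[e]];
    dp[from[e]] -= f;
    dp[to[e]] += f;
  }
}

// Mean-field master-equation integration with classic RK4 on a fixed
// grid. conc and volt are sampled on the half-step grid (length
// 2*nSteps + 1). Occupancies are renormalized each step; leaving
// [-1e-6, 1 + 1e-6] aborts with advice to reduce dt.
// [[Rcpp::export(name = ".meanfield_rk4")]]
List meanfield_rk4(NumericVector p0, IntegerVector from, IntegerVector to,
                   IntegerVector type, NumericVector rate,
                   NumericVector slope, NumericVector conc,
                   NumericVector volt, double dt, int openState,
                   int saveEvery) {
  const int ns = p0.size();
  const int nSteps = (conc.size() - 1) / 2;
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  const int nSave = nSteps / saveEvery + 1;
  NumericMatrix occ(nSave, ns);
  NumericVector tSave(nSave);
  int si = 0;
  double auc = 0.0, peak = p[openState], peakT = 0.0, maxDrift = 0.0;
  double prevOpen = p[openState];
  for (int c = 0; c < ns; ++c) occ(0, c) = p[c];
  tSave[0] = 0.0;
  si = 1;
  const int m = from.size();
  for (int s = 0; s < nSteps; ++s) {
    const double g0 = conc[2 * s], gh = conc[2 * s + 1],
                 g1 = conc[2 * s + 2];
    const double v0 = volt[2 * s], vh = volt[2 * s + 1],
                 v1 = volt[2 * s + 2];
    // stiffness guard: sub-step when the total outflux rate approaches
    // the RK4 stability limit (transients right after a release)
    double rtot = 0.0;
    for (int e = 0; e < m; ++e) {
      double r0 = rate_at(type[e], rate[e], slope[e], g0, v0);
      double r1 = rate_at(type[e], rate[e], slope[e], gh, vh);
      double r2 = rate_at(type[e], rate[e], slope[e], g1, v1);
      rtot += std::max(r0, std::max(r1, r2));
    }
    int nSub = (int)std::ceil(rtot * dt / 0.5);
    if (nSub < 1) nSub = 1;
    if (nSub > 256) nSub = 256;
    const double h = dt / nSub;
    // piecewise-linear ligand/voltage through the three samples
    auto interp = [&](double g_0, double g_h, double g_1, double f) {
      return f <= 0.5 ? g_0 + (g_h - g_0) * (2.0 * f)
                      : g_h + (g_1 - g_h) * (2.0 * f - 1.0);
    };
    for (int sub = 0; sub < nSub; ++sub) {
      const double fa = (double)sub / nSub;
      const double fm = (sub + 0.5) / nSub;
      const double fb = (double)(sub + 1) / nSub;
      const double ga = interp(g0, gh, g1, fa), va = interp(v0, vh, v1, fa);
      const double gm = interp(g0, gh, g1, fm), vm = interp(v0, vh, v1, fm);
      const double gb = interp(g0, gh, g1, fb), vb = interp(v0, vh, v1, fb);
      deriv(p, k1, from, to, type, rate, slope, ga, va);
      for (int c = 0; c < ns; ++c) tmp[c] = p[c] + 0.5 * h * k1[c];
      deriv(tmp, k2, from, to, type, rate, slope, gm, vm);
      for (int c = 0; c < ns; ++c) tmp[c] = p[c] + 0.5 * h * k2[c];
      deriv(tmp, k3, from, to, type, rate, slope, gm, vm);
      for (int c = 0; c < ns; ++c) tmp[c] = p[c] + h * k3[c];
      deriv(tmp, k4, from, to, type, rate, slope, gb, vb);
      for (int c = 0; c < ns; ++c)
        p[c] += h / 6.0 * (k1[c] + 2.0 * k2[c] + 2.0 * k3[c] + k4[c]);
    }
    double sum = 0.0;
    for (int c = 0; c < ns; ++c) sum += p[c];
    double drift = std::fabs(sum - 1.0);
    if (drift > maxDrift) maxDrift = drift;
    for (int c = 0; c < ns; ++c) {
      if (p[c] < -1e-6 || p[c] > 1.0 + 1e-6)
        stop("integration unstable (occupancy %.3g); use a smaller dt",
             p[c]);
      if (p[c] < 0.0) p[c] = 0.0;
    }
    for (int c = 0; c < ns; ++c) p[c] /= sum;
    const double open = p[openState];
    auc += 0.5 * (prevOpen + open) * dt;
    prevOpen = open;
    const double t = (s + 1) * dt;
    if (open > peak) { peak = open; peakT = t; }
    if ((s + 1) % saveEvery == 0 && si < nSave) {
      for (int c = 0; c < ns; ++c) occ(si, c) = p[c];
      tSave[si] = t;
      ++si;
    }
  }
  return List::create(_["time"] = tSave, _["occupancy"] = occ,
                      _["auc"] = auc, _["peak"] = peak,
                      _["peakTime"] = peakT, _["maxDrift"] = maxDrift);
}

// Stochastic per-receptor Markov chains with fixed-step thinning: at
// each step a receptor takes at most one transition, chosen with
// probability rate * dt. Uses R's RNG so results are reproducible with
// set.seed(). Returns per-trial open-count traces (saved every
// saveEvery steps) and per-trial AUCs at full resolution.
// [[Rcpp::export(name = ".stochastic_sim")]]
List stochastic_sim(int nReceptors, int nTrials, int initState,
                    IntegerVector from, IntegerVector to,
                    IntegerVector type, NumericVector rate,
                    NumericVector slope, NumericVector conc,
                    NumericVector volt, double dt, int openState,
                    int saveEvery) {
  const int nSteps = (conc.size() - 1) / 2;
  const int m = from.size();
  const int nSave = nSteps / saveEvery + 1;
  NumericMatrix traces(nTrials, nSave);
  NumericVector aucs(nTrials);
  NumericVector tSave(nSave);
  for (int s = 0; s <= nSteps; s += saveEvery)
    tSave[s / saveEvery] = s * dt;
  RNGScope scope;
  for (int tr = 0; tr < nTrials; ++tr) {
    std::vector<int> state(nReceptors, initState);
    int nOpen = 0;
    for (int i = 0; i < nReceptors; ++i)
      if (state[i] == openState) ++nOpen;
    traces(tr, 0) = nOpen;
    double auc = 0.0;
    int prevOpen = nOpen;
    for (int s = 0; s < nSteps; ++s) {
      const double g = conc[2 * s + 1];  // midpoint sample
      const double v = volt[2 * s + 1];
      // keep per-substep jump probabilities small even during the
      // release transient
      double rtot = 0.0;
      for (int e = 0; e < m; ++e)
        rtot += rate_at(type[e], rate[e], slope[e], g, v);
      int nSub = (int)std::ceil(rtot * dt / 0.2);
      if (nSub < 1) nSub = 1;
      if (nSub > 256) nSub = 256;
      const double h = dt / nSub;
      for (int i = 0; i < nReceptors; ++i) {
        for (int sub = 0; sub < nSub; ++sub) {
          double u = unif_rand();
          double acc = 0.0;
          for (int e = 0; e < m; ++e) {
            if (from[e] != state[i]) continue;
            acc += rate_at(type[e], rate[e], slope[e], g, v) * h;
            if (u < acc) {
              if (state[i] == openState) --nOpen;
              state[i] = to[e];
              if (state[i] == openState) ++nOpen;
              break;
            }
          }
        }
      }
      auc += 0.5 * (prevOpen + nOpen) * dt;
      prevOpen = nOpen;
      if ((s + 1) % saveEvery == 0)
        traces(tr, (s + 1) / saveEvery) = nOpen;
    }
    aucs[tr] = auc;
  }
  return List::create(_["time"] = tSave, _["traces"] = traces,
                      _["aucs"] = aucs);
}
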