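#include <Rcpp.h>
using namespace Rcpp;

// Mixture marginal likelihood for dual-stimulus spike counts, conditioning the
// component rates on posterior draws (lamA, lamB) and integrating the mixing
// weight alpha over a uniform prior with composite Simpson quadrature.
//
// Returns the log marginal likelihood, a delta-method Monte-Carlo SE on the
// log scale, the posterior mean and equal-tail 95% interval of alpha, and the
// per-presentation posterior probability that each count arose from the A
// (first) component, averaged over the same (alpha, lamA, lamB) weights.
// logw holds per-node log weights (log(1/R) for plain Monte-Carlo draws;
// log cell masses for deterministic probability-cell grids).
// [[Rcpp::export]]
List cpp_mixture_marglik(IntegerVector y, NumericVector lamA,
                         NumericVector lamB, int nAlpha,
                         NumericVector logw, bool want_scores) {
  const int m = y.size();
  const int R = lamA.size();
  if (R < 1) stop("need at least one rate draw");
  if (logw.size() != R) stop("logw must match the rate draws");
  if (nAlpha < 3 || nAlpha % 2 == 0) stop("nAlpha must be odd and >= 3");
  if (m == 0) stop("empty count vector; handle m == 0 in the caller");

  // Simpson nodes/weights on [0, 1]
  std::vector<double> anode(nAlpha), aw(nAlpha);
  const double h = 1.0 / (nAlpha - 1);
  for (int k = 0; k < nAlpha; ++k) {
    anode[k] = k * h;
    double w = (k == 0 || k == nAlpha - 1) ? 1.0 : (k % 2 == 1 ? 4.0 : 2.0);
    aw[k] = w * h / 3.0;
  }

  // log Poisson pmfs per draw x count, and per-count max for rescaling
  NumericMatrix la(R, m), lb(R, m);
  std::vector<double> Cr(R, 0.0);
  for (int r = 0; r < R; ++r) {
    double c = 0.0;
    for (int j = 0; j < m; ++j) {
      double pa = R::dpois(y[j], lamA[r], 1);
      double pb = R::dpois(y[j], lamB[r], 1);
      double M = std::max(pa, pb);
      la(r, j) = std::exp(pa - M);  // scaled to max 1
      lb(r, j) = std::exp(pb - M);
      c += M;
    }
    Cr[r] = c;
  }

  // logf(r, k) = log integrand at alpha node k for draw r
  NumericMatrix logf(R, nAlpha);
  for (int r = 0; r < R; ++r) {
    for (int k = 0; k < nAlpha; ++k) {
      const double a = anode[k], b = 1.0 - anode[k];
      double prod = 1.0;
      double lscale = 0.0;
      for (int j = 0; j < m; ++j) {
        prod *= a * la(r, j) + b * lb(r, j);
        if (prod > 0.0 && prod < 1e-280) {
          prod *= 1e280;
          lscale -= 280.0 * M_LN10;
        }
      }
      logf(r, k) = (prod > 0.0) ? Cr[r] + std::log(prod) + lscale
                                : R_NegInf;
    }
  }

  // per-node alpha integral (weight included), then log-sum-exp across nodes
  std::vector<double> Ilog(R);
  for (int r = 0; r < R; ++r) {
    double mx = R_NegInf;
    for (int k = 0; k < nAlpha; ++k) mx = std::max(mx, logf(r, k));
    if (!R_FINITE(mx)) { Ilog[r] = R_NegInf; continue; }
    double s = 0.0;
    for (int k = 0; k < nAlpha; ++k)
      if (R_FINITE(logf(r, k))) s += aw[k] * std::exp(logf(r, k) - mx);
    Ilog[r] = mx + std::log(s) + logw[r];
  }
  double M1 = R_NegInf;
  for (int r = 0; r < R; ++r) M1 = std::max(M1, Ilog[r]);
  if (!R_FINITE(M1)) stop("all mixture integrands underflowed to zero");
  double sm = 0.0, sm2 = 0.0;
  for (int r = 0; r < R; ++r) {
    double v = std::exp(Ilog[r] - M1);
    sm += v;
    sm2 += v * v;
  }
  const double mean_v = sm / R;
  const double var_v = (R > 1) ? (sm2 - R * mean_v * mean_v) / (R - 1) : 0.0;
  const double logml = M1 + std::log(sm);
  // interpretable for equal-weight Monte-Carlo nodes only (scale cancels)
  const double mc_se =
      (R > 1) ? std::sqrt(std::max(var_v, 0.0) / R) / mean_v : NA_REAL;

  if (!want_scores)
    return List::create(_["logml"] = logml, _["mc_se"] = mc_se,
                        _["alpha_mean"] = NA_REAL,
                        _["alpha_ci"] = NumericVector::create(NA_REAL, NA_REAL),
                        _["scores"] = NumericVector(0));

  // alpha posterior on the grid, and per-presentation component posteriors
  double M2 = R_NegInf;
  for (int r = 0; r < R; ++r)
    for (int k = 0; k < nAlpha; ++k)
      M2 = std::max(M2, logf(r, k) + logw[r]);
  std::vector<double> Wk(nAlpha, 0.0);
  std::vector<double> numA(m, 0.0), numB(m, 0.0);
  for (int r = 0; r < R; ++r) {
    for (int k = 0; k < nAlpha; ++k) {
      if (!R_FINITE(logf(r, k))) continue;
      const double e = aw[k] * std::exp(logf(r, k) + logw[r] - M2);
      if (e == 0.0) continue;
      Wk[k] += e;
      const double a = anode[k], b = 1.0 - anode[k];
      for (int j = 0; j < m; ++j) {
        const double t = a * la(r, j);
        const double u = b * lb(r, j);
        const double d = t + u;
        if (d > 0.0) {
          numA[j] += e * (t / d);
          numB[j] += e * (u / d);
        }
      }
    }
  }
  double Wtot = 0.0, amean = 0.0;
  for (int k = 0; k < nAlpha; ++k) Wtot += Wk[k];
  for (int k = 0; k < nAlpha; ++k) amean += anode[k] * Wk[k] / Wtot;
  double cum = 0.0, alo = 0.0, ahi = 1.0;
  bool lo_set = false;
  for (int k = 0; k < nAlpha; ++k) {
    cum += Wk[k] / Wtot;
    if (!lo_set && cum >= 0.025) { alo = anode[k]; lo_set = true; }
    if (cum >= 0.975) { ahi = anode[k]; break; }
  }
  if (alo > amean) alo = amean;
  if (ahi < amean) ahi = amean;
  NumericVector scores(m);
  for (int j = 0; j < m; ++j) scores[j] = numA[j] / (numA[j] + numB[j]);

  return List::create(_["logml"] = logml, _["mc_se"] = mc_se,
                      _["alpha_mean"] = amean,
                      _["alpha_ci"] = NumericVector::create(alo, ahi),
                      _["scores"] = scores);
}

// Chi-square GOF statistic against Poisson at the sample-mean rate, on integer
// bins 0,1,...,T-1 plus a pooled right tail [T, inf) chosen so the tail's
// expected count is >= 1 (largest such T).
static double gof_stat(const std::vector<int>& y) {
  const int n = (int)y.size();
  long S = 0;
  int ymax = 0;
  for (int v : y) { S += v; ymax = std::max(ymax, v); }
  const double lam = (double)S / n;
  if (lam <= 0.0) return 0.0;  // all-zero sample: single bin, perfect fit
  // largest T >= 1 with n * P(X >= T) >= 1
  int T = 1;
  const int cap = (int)(lam + 20.0 * std::sqrt(lam) + 20.0);
  while (T < cap && n * R::ppois(T, lam, 0, 0) >= 1.0) ++T;
  std::vector<int> O(T + 1, 0);
  for (int v : y) O[std::min(v, T)]++;
  double stat = 0.0;
  for (int k = 0; k < T; ++k) {
    const double E = n * R::dpois(k, lam, 0);
    if (E > 0.0) {
      const double d = O[k] - E;
      stat += d * d / E;
    } else if (O[k] > 0) {
      stat += 1e12;
    }
  }
  const double Etail = n * R::ppois(T - 1, lam, 0, 0);
  if (Etail > 0.0) {
    const double d = O[T] - Etail;
    stat += d * d / Etail;
  } else if (O[T] > 0) {
    stat += 1e12;
  }
  return stat;
}

// Monte-Carlo p-value: simulate n_mc same-size samples from Poisson at the
// observed sample-mean rate, refit the rate and rebin per simulation, and
// apply the add-one correction so p > 0. Uses R's RNG.
// [[Rcpp::export]]
double cpp_gof_pvalue(IntegerVector y, int n_mc) {
  const int n = y.size();
  std::vector<int> yy(y.begin(), y.end());
  const double obs = gof_stat(yy);
  double lam = 0.0;
  for (int v : yy) lam += v;
  lam /= n;
  int ge = 0;
  std::vector<int> sim(n);
  for (int s = 0; s < n_mc; ++s) {
    for (int i = 0; i < n; ++i) sim[i] = (int)R::rpois(lam);
    if (gof_stat(sim) >= obs) ++ge;
  }
  return (1.0 + ge) / (n_mc + 1.0);
}
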