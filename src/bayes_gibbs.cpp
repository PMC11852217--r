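#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs samplers for whole-genome regression with the Bayesian-alphabet
// priors. Model: y = mu + X beta + e, e ~ N(0, sigma2_e I), genotype columns
// centered in R before the call. Families differ only in the prior on beta:
//   0 BRR  : beta_j ~ N(0, s2b) common, s2b ~ scaled-inv-chisq(dfb, Sb)
//   1 A    : per-locus s2b_j ~ scaled-inv-chisq(dfb, Sb), Sb ~ Gamma(rS, sS)
//   2 B    : spike-slab indicator, per-locus slab variances, pi ~ Beta,
//            Sb ~ Gamma(rS, sS)
//   3 C    : spike-slab indicator, common slab variance, pi ~ Beta
//   4 BL   : beta_j ~ N(0, tau2_j sigma2_e), 1/tau2_j inverse-Gaussian,
//            lambda2 ~ Gamma(rL, sL)
// All draws go through R's RNG so a set.seed() in R fixes the chain.

static double rscinv(double df, double SS) {
  // scaled-inverse-chi-square draw given df and total sum-of-squares SS
  return SS / R::rchisq(df);
}

static double rinvgauss1(double mu, double lambda) {
  if (mu > 1e8) mu = 1e8;
  double z = norm_rand();
  double z2 = z * z;
  double x = mu + mu * mu * z2 / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * z2 + mu * mu * z2 * z2);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export]]
List bayes_gibbs_cpp(NumericMatrix X, NumericVector y, int family, List hp,
                     int n_iter, int burn_in, int thin, bool update_varb,
                     bool update_vare, bool update_pi, bool keep_trace) {
  const int n = X.nrow(), p = X.ncol();
  const double dfb = as<double>(hp["dfb"]);
  double Sb = as<double>(hp["Sb"]);
  const double dfe = as<double>(hp["dfe"]);
  const double Se = as<double>(hp["Se"]);
  const double pi0 = as<double>(hp["pi0"]);
  const double p0 = as<double>(hp["p0"]);
  const double rS = as<double>(hp["rS"]);
  const double sS = as<double>(hp["sS"]);
  const double rL = as<double>(hp["rL"]);
  const double sL = as<double>(hp["sL"]);
  double lambda2 = as<double>(hp["lambda2"]);
  double vare = as<double>(hp["vare"]);
  double s2b = as<double>(hp["varb"]);

  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += y[i];
  mu /= n;
  std::vector<double> beta(p, 0.0), e(n), s2bj(p, s2b), tau2(p, 1.0);
  std::vector<int> delta(p, 1);
  double pi = (family == 2 || family == 3) ? pi0 : 1.0;
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  // posterior accumulators
  std::vector<double> b_sum(p, 0.0), b_ss(p, 0.0), d_sum(p, 0.0),
      fit_sum(n, 0.0);
  double mu_sum = 0.0, vare_sum = 0.0, varb_sum = 0.0, pi_sum = 0.0,
         l2_sum = 0.0, vare_ss = 0.0;
  int kept = 0;
  const int n_keep =
      (n_iter > burn_in) ? ((n_iter - burn_in - 1) / thin + 1) : 0;
  NumericMatrix trace;
  if (keep_trace) trace = NumericMatrix(n_keep, p);

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = R::rnorm(mu + ebar, std::sqrt(vare / n));
    for (int i = 0; i < n; ++i) e[i] -= (mu_new - mu);
    mu = mu_new;

    // marker effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
      double r = xtx[j] * beta[j];
      for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
      double bnew;
      if (family == 2 || family == 3) {
        const double v = (family == 2) ? s2bj[j] : s2b;
        const double logBF =
            0.5 * r * r * v / (vare * (xtx[j] * v + vare)) -
            0.5 * std::log1p(xtx[j] * v / vare);
        const double logodds = std::log(pi / (1.0 - pi + 1e-300)) + logBF;
        const double p1 = 1.0 / (1.0 + std::exp(-logodds));
        if (unif_rand() < p1) {
          delta[j] = 1;
          const double C = xtx[j] + vare / v;
          bnew = R::rnorm(r / C, std::sqrt(vare / C));
        } else {
          delta[j] = 0;
          bnew = 0.0;
        }
      } else {
        double v;
        if (family == 0) v = s2b;
        else if (family == 1) v = s2bj[j];
        else v = tau2[j] * vare; // BL
        const double C = xtx[j] + vare / v;
        bnew = R::rnorm(r / C, std::sqrt(vare / C));
      }
      if (bnew != beta[j]) {
        const double d = beta[j] - bnew;
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
        beta[j] = bnew;
      }
    }

    // prior-variance structure
    if (update_varb) {
      if (family == 0) {
        double ssb = 0.0;
        for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
        s2b = rscinv(dfb + p, ssb + dfb * Sb);
      } else if (family == 1 || family == 2) {
        double sum_inv = 0.0;
        for (int j = 0; j < p; ++j) {
          if (family == 1 || delta[j] == 1)
            s2bj[j] = rscinv(dfb + 1.0, beta[j] * beta[j] + dfb * Sb);
          else
            s2bj[j] = rscinv(dfb, dfb * Sb); // prior draw for excluded loci
          sum_inv += 1.0 / s2bj[j];
        }
        if (rS > 0.0)
          Sb = R::rgamma(rS + 0.5 * p * dfb, 1.0 / (sS + 0.5 * dfb * sum_inv));
      } else if (family == 3) {
        double ssb = 0.0;
        int k = 0;
        for (int j = 0; j < p; ++j)
          if (delta[j] == 1) { ssb += beta[j] * beta[j]; ++k; }
        s2b = rscinv(dfb + k, ssb + dfb * Sb);
      } else { // BL
        double sum_tau2 = 0.0;
        for (int j = 0; j < p; ++j) {
          const double b2 = beta[j] * beta[j];
          const double m =
              (b2 > 1e-12) ? std::sqrt(lambda2 * vare / b2) : 1e8;
          const double itau = rinvgauss1(m, lambda2);
          tau2[j] = 1.0 / itau;
          sum_tau2 += tau2[j];
        }
        lambda2 = R::rgamma(p + rL, 1.0 / (0.5 * sum_tau2 + sL));
      }
    }

    if ((family == 2 || family == 3) && update_pi) {
      int k = 0;
      for (int j = 0; j < p; ++j) k += delta[j];
      pi = R::rbeta(p0 * pi0 + k, p0 * (1.0 - pi0) + p - k);
      if (pi < 1e-6) pi = 1e-6;
      if (pi > 1.0 - 1e-6) pi = 1.0 - 1e-6;
    }

    if (update_vare) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += e[i] * e[i];
      double df = n + dfe;
      if (family == 4) { // beta variance proportional to sigma2_e
        for (int j = 0; j < p; ++j) ss += beta[j] * beta[j] / tau2[j];
        df += p;
      }
      vare = rscinv(df, ss + dfe * Se);
    }
    if (!R_finite(vare) || !R_finite(mu))
      stop("divergent chain at iteration %d", it + 1);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        b_sum[j] += beta[j];
        b_ss[j] += beta[j] * beta[j];
        d_sum[j] += delta[j];
        if (keep_trace) trace(kept, j) = beta[j];
      }
      for (int i = 0; i < n; ++i) fit_sum[i] += y[i] - e[i];
      mu_sum += mu;
      vare_sum += vare;
      vare_ss += vare * vare;
      pi_sum += pi;
      l2_sum += lambda2;
      if (family == 0 || family == 3) varb_sum += s2b;
      else if (family == 1 || family == 2) {
        double m = 0.0;
        for (int j = 0; j < p; ++j) m += s2bj[j];
        varb_sum += m / p;
      } else {
        double m = 0.0;
        for (int j = 0; j < p; ++j) m += tau2[j] * vare;
        varb_sum += m / p;
      }
      ++kept;
    }
  }

  NumericVector bm(p), bs(p), dm(p), fm(n);
  for (int j = 0; j < p; ++j) {
    bm[j] = b_sum[j] / kept;
    const double v = b_ss[j] / kept - bm[j] * bm[j];
    bs[j] = std::sqrt(v > 0.0 ? v : 0.0);
    dm[j] = d_sum[j] / kept;
  }
  for (int i = 0; i < n; ++i) fm[i] = fit_sum[i] / kept;
  const double vem = vare_sum / kept;
  double vesd = vare_ss / kept - vem * vem;
  vesd = std::sqrt(vesd > 0.0 ? vesd : 0.0);
  List out = List::create(
      _["beta_mean"] = bm, _["beta_sd"] = bs, _["incl_prob"] = dm,
      _["mu"] = mu_sum / kept, _["vare"] = vem, _["vare_sd"] = vesd,
      _["varb"] = varb_sum / kept, _["pi"] = pi_sum / kept,
      _["lambda2"] = l2_sum / kept, _["fitted"] = fm, _["n_kept"] = kept);
  if (keep_trace) out["trace"] = trace;
  return out;
}
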