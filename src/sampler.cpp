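// Metropolis-within-Gibbs sampler for the partially nested heteroscedastic
// two-level model
//
//   y_i  ~ N(b0, s2eC)                     control arm (no clustering)
//   y_ij ~ N(b0 + b1 + u_j, s2eU)          treatment arm, cluster j = 1..c
//   u_j  ~ N(0, s2U)
//
// All updates work on sufficient statistics, so one iteration costs O(c)
// regardless of the number of subjects. The same internal routines back both
// the full chain runner and the single-step entry points used by oracle tests.
//
// Uses R's RNG throughout: seeding via set.seed() on the R side makes every
// draw reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// prior family codes
static const int FAM_UNIFORM = 0;
static const int FAM_GAMMA = 1;

struct VarPrior {
  int family;
  double shape;  // gamma shape (k)
  double scale;  // gamma scale (theta); prior mean = k * theta
  double upper;  // uniform upper bound
};

// log of the gamma-prior M-H target on lambda = log(sigma2):
// Gaussian likelihood of n residuals with sum of squares S, gamma(k, theta)
// prior on sigma2, plus the +lambda Jacobian of the log transform.
static inline double loglik_lambda_gamma(double lambda, double n, double S,
                                         double shape, double scale) {
  double sigma2 = std::exp(lambda);
  return (shape - 0.5 * n) * lambda - 0.5 * S / sigma2 - sigma2 / scale;
}

// One random-walk M-H step on lambda = log(sigma2) under a gamma prior.
// Returns the new sigma2; *accepted set to 1 on acceptance.
static double mh_step_gamma_variance(double sigma2, double n, double S,
                                     double shape, double scale,
                                     double rw_step, int *accepted) {
  double lambda = std::log(sigma2);
  double lambda_prop = lambda + R::rnorm(0.0, rw_step);
  double log_ratio = loglik_lambda_gamma(lambda_prop, n, S, shape, scale) -
                     loglik_lambda_gamma(lambda, n, S, shape, scale);
  *accepted = 0;
  if (log_ratio >= 0.0 || std::log(R::runif(0.0, 1.0)) < log_ratio) {
    *accepted = 1;
    return std::exp(lambda_prop);
  }
  return sigma2;
}

// Exact draw from the full conditional of a variance under a flat U(0, upper)
// prior: kernel x^(-n/2) exp(-S/(2x)) on (0, upper), i.e. an inverse-gamma
// with shape n/2 - 1 and rate S/2 truncated to (0, upper). Drawn by
// inverse-CDF on the precision scale (upper-tail parameterization so the
// truncation stays accurate when the untruncated mass sits above `upper`).
// Falls back to a reflected random-walk M-H step when the shape is
// non-positive or the tail mass underflows; *fallback set to 1 in that case.
static double draw_trunc_invgamma(double sigma2_cur, double n, double S,
                                  double upper, int *fallback) {
  *fallback = 0;
  double shape = 0.5 * n - 1.0;
  double rate = 0.5 * S;
  if (shape > 0.0 && rate > 0.0) {
    // precision tau = 1/sigma2 ~ Gamma(shape, rate) restricted to tau > 1/upper
    double p_tail = R::pgamma(1.0 / upper, shape, 1.0 / rate,
                              /*lower_tail=*/0, /*log_p=*/0);
    if (p_tail > 1e-300) {
      double v = R::runif(0.0, 1.0) * p_tail;
      double tau = R::qgamma(v, shape, 1.0 / rate, /*lower_tail=*/0, /*log_p=*/0);
      double out = 1.0 / tau;
      if (R_finite(out) && out > 0.0 && out < upper) return out;
    }
  } else if (rate <= 0.0) {
    // degenerate all-zero residuals: conditional piles up at 0+
    return 1e-12;
  }
  // reflected random-walk fallback, symmetric proposal on (0, upper)
  *fallback = 1;
  double prop = sigma2_cur + R::rnorm(0.0, 0.1 * upper);
  for (int r = 0; r < 64; ++r) {  // reflect into the support
    if (prop < 0.0) prop = -prop;
    else if (prop > upper) prop = 2.0 * upper - prop;
    else break;
  }
  if (prop <= 0.0 || prop >= upper) return sigma2_cur;
  double log_ratio =
      (-0.5 * n) * (std::log(prop) - std::log(sigma2_cur)) -
      0.5 * S * (1.0 / prop - 1.0 / sigma2_cur);
  if (log_ratio >= 0.0 || std::log(R::runif(0.0, 1.0)) < log_ratio)
    return prop;
  return sigma2_cur;
}

struct SuffStats {
  double nC, sumC, sumsqC;  // control arm
  int c, m;                 // treatment clusters
  NumericVector sumJ;       // per-cluster sums
  NumericVector sumsqJ;     // per-cluster sums of squares
  double sumT, NT;
};

// residual sum of squares in the control arm given b0
static inline double ss_control(const SuffStats &st, double b0) {
  return st.sumsqC - 2.0 * b0 * st.sumC + st.nC * b0 * b0;
}

// residual sum of squares in the treatment arm given b0, b1, u
static inline double ss_treatment(const SuffStats &st, double b0, double b1,
                                  const std::vector<double> &u) {
  double ss = 0.0;
  for (int j = 0; j < st.c; ++j) {
    double a = b0 + b1 + u[j];
    ss += st.sumsqJ[j] - 2.0 * a * st.sumJ[j] + st.m * a * a;
  }
  return ss;
}

// Gibbs update of (b0, b1, u) from their exact normal full conditionals.
static void update_location(const SuffStats &st, double s2U, double s2eC,
                            double s2eU, double b0m, double b0v, double b1m,
                            double b1v, double *b0, double *b1,
                            std::vector<double> &u) {
  double sumU = 0.0;
  for (int j = 0; j < st.c; ++j) sumU += u[j];

  // b0 | .
  double prec = st.nC / s2eC + st.NT / s2eU + 1.0 / b0v;
  double num = st.sumC / s2eC +
               (st.sumT - st.NT * (*b1) - st.m * sumU) / s2eU + b0m / b0v;
  *b0 = num / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);

  // b1 | .
  prec = st.NT / s2eU + 1.0 / b1v;
  num = (st.sumT - st.NT * (*b0) - st.m * sumU) / s2eU + b1m / b1v;
  *b1 = num / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);

  // u_j | . : precision m/s2eU + 1/s2U
  double uprec = st.m / s2eU + 1.0 / s2U;
  double usd = 1.0 / std::sqrt(uprec);
  for (int j = 0; j < st.c; ++j) {
    double unum = (st.sumJ[j] - st.m * (*b0 + *b1)) / s2eU;
    u[j] = unum / uprec + R::rnorm(0.0, 1.0) * usd;
  }
}

static SuffStats make_stats(double nC, double sumC, double sumsqC, int m,
                            NumericVector sumJ, NumericVector sumsqJ) {
  SuffStats st;
  st.nC = nC; st.sumC = sumC; st.sumsqC = sumsqC;
  st.c = sumJ.size(); st.m = m;
  st.sumJ = sumJ; st.sumsqJ = sumsqJ;
  st.sumT = Rcpp::sum(sumJ);
  st.NT = (double)st.c * m;
  return st;
}

static VarPrior make_prior(NumericVector spec) {
  // spec: family, shape, scale, upper
  VarPrior p;
  p.family = (int)spec[0];
  p.shape = spec[1]; p.scale = spec[2]; p.upper = spec[3];
  return p;
}

// Update one variance component from its full conditional (uniform prior:
// exact truncated inverse-gamma; gamma prior: one M-H step on log sigma2).
static double update_variance(double sigma2, double n, double S,
                              const VarPrior &pr, double rw_step,
                              int *accepted, int *fallback) {
  *accepted = 0; *fallback = 0;
  if (pr.family == FAM_UNIFORM) {
    double out = draw_trunc_invgamma(sigma2, n, S, pr.upper, fallback);
    *accepted = 1;
    return out;
  }
  return mh_step_gamma_variance(sigma2, n, S, pr.shape, pr.scale, rw_step,
                                accepted);
}

// [[Rcpp::export]]
List run_chain_cpp(double nC, double sumC, double sumsqC, int m,
                   NumericVector sumJ, NumericVector sumsqJ,
                   NumericVector prior_U, NumericVector prior_eC,
                   NumericVector prior_eU, double b0m, double b0v, double b1m,
                   double b1v, int n_iter, int n_burn, int thin,
                   double rw_step, bool adapt, NumericVector init,
                   NumericVector init_u, bool fix_variances) {
  SuffStats st = make_stats(nC, sumC, sumsqC, m, sumJ, sumsqJ);
  VarPrior prU = make_prior(prior_U);
  VarPrior preC = make_prior(prior_eC);
  VarPrior preU = make_prior(prior_eU);

  double b0 = init[0], b1 = init[1];
  double s2U = init[2], s2eC = init[3], s2eU = init[4];
  std::vector<double> u(init_u.begin(), init_u.end());
  if ((int)u.size() != st.c) stop("init_u length must equal cluster count");

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, 5);
  colnames(draws) = CharacterVector::create("b0", "b1", "sigma2_U",
                                            "sigma2_eC", "sigma2_eU");

  // per-component M-H bookkeeping (post burn-in) and adaptive step sizes
  double step[3] = {rw_step, rw_step, rw_step};
  long acc[3] = {0, 0, 0}, att[3] = {0, 0, 0};
  long adapt_acc[3] = {0, 0, 0}, adapt_att[3] = {0, 0, 0};
  long fallbacks = 0;
  int keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    update_location(st, s2U, s2eC, s2eU, b0m, b0v, b1m, b1v, &b0, &b1, u);

    if (!fix_variances) {
      int a, f;
      bool burning = it < n_burn;

      double S_U = 0.0;
      for (int j = 0; j < st.c; ++j) S_U += u[j] * u[j];
      s2U = update_variance(s2U, (double)st.c, S_U, prU, step[0], &a, &f);
      fallbacks += f;
      if (prU.family == FAM_GAMMA) {
        if (burning) { adapt_acc[0] += a; adapt_att[0]++; }
        else { acc[0] += a; att[0]++; }
      }

      s2eC = update_variance(s2eC, st.nC, ss_control(st, b0), preC, step[1],
                             &a, &f);
      fallbacks += f;
      if (preC.family == FAM_GAMMA) {
        if (burning) { adapt_acc[1] += a; adapt_att[1]++; }
        else { acc[1] += a; att[1]++; }
      }

      s2eU = update_variance(s2eU, st.NT, ss_treatment(st, b0, b1, u), preU,
                             step[2], &a, &f);
      fallbacks += f;
      if (preU.family == FAM_GAMMA) {
        if (burning) { adapt_acc[2] += a; adapt_att[2]++; }
        else { acc[2] += a; att[2]++; }
      }

      // burn-in-only step-size adaptation toward 30-45% acceptance;
      // frozen afterwards so retained draws keep detailed balance
      if (adapt && burning && ((it + 1) % 100 == 0)) {
        for (int k = 0; k < 3; ++k) {
          if (adapt_att[k] >= 50) {
            double rate = (double)adapt_acc[k] / adapt_att[k];
            if (rate < 0.30) step[k] *= 0.8;
            else if (rate > 0.45) step[k] *= 1.25;
            adapt_acc[k] = 0; adapt_att[k] = 0;
          }
        }
      }
    }

    if (it >= n_burn && ((it - n_burn) % thin == thin - 1)) {
      draws(keep, 0) = b0;
      draws(keep, 1) = b1;
      draws(keep, 2) = s2U;
      draws(keep, 3) = s2eC;
      draws(keep, 4) = s2eU;
      ++keep;
    }
  }

  NumericVector acc_rate(3, NA_REAL);
  for (int k = 0; k < 3; ++k)
    if (att[k] > 0) acc_rate[k] = (double)acc[k] / att[k];
  acc_rate.names() = CharacterVector::create("sigma2_U", "sigma2_eC",
                                             "sigma2_eU");

  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["fallbacks"] = (double)fallbacks,
                      _["final_step"] = NumericVector::create(step[0], step[1],
                                                              step[2]));
}

// Single Gibbs sweep over (b0, b1, u) with variances held fixed; exposed so
// oracle tests can exercise the exact code path used inside run_chain_cpp.
// [[Rcpp::export]]
List location_step_cpp(double nC, double sumC, double sumsqC, int m,
                       NumericVector sumJ, NumericVector sumsqJ, double s2U,
                       double s2eC, double s2eU, double b0m, double b0v,
                       double b1m, double b1v, double b0, double b1,
                       NumericVector u_in) {
  SuffStats st = make_stats(nC, sumC, sumsqC, m, sumJ, sumsqJ);
  std::vector<double> u(u_in.begin(), u_in.end());
  update_location(st, s2U, s2eC, s2eU, b0m, b0v, b1m, b1v, &b0, &b1, u);
  return List::create(_["b0"] = b0, _["b1"] = b1,
                      _["u"] = NumericVector(u.begin(), u.end()));
}

// n_draws independent draws from the truncated inverse-gamma full
// conditional (uniform-prior variance update); same routine as the chain.
// [[Rcpp::export]]
NumericVector rtrunc_invgamma_cpp(int n_draws, double n, double S,
                                  double upper) {
  NumericVector out(n_draws);
  int fb;
  double cur = 0.5 * upper;
  for (int i = 0; i < n_draws; ++i) {
    cur = draw_trunc_invgamma(cur, n, S, upper, &fb);
    out[i] = cur;
  }
  return out;
}

// A run of gamma-prior M-H variance updates on a fixed residual configuration
// (n residuals, sum of squares S); returns the sigma2 chain and the
// acceptance count. Same kernel as the chain's gamma variance block.
// [[Rcpp::export]]
List mh_gamma_variance_chain_cpp(int n_steps, double n, double S, double shape,
                                 double scale, double rw_step, double init) {
  NumericVector out(n_steps);
  double cur = init;
  long n_acc = 0;
  int a;
  for (int i = 0; i < n_steps; ++i) {
    cur = mh_step_gamma_variance(cur, n, S, shape, scale, rw_step, &a);
    n_acc += a;
    out[i] = cur;
  }
  return List::create(_["sigma2"] = out, _["n_accepted"] = (double)n_acc);
}
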