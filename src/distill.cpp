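#include <Rcpp.h>
using namespace Rcpp;

// Univariate negative-binomial fit used by the distilled test statistic.
//
// Model: y_i ~ NegBin(mu_i, alpha) with log(mu_i) = beta + o_i over the
// supplied cells only, where o_i are fixed offsets from the reduced
// (covariates-only) fit and theta = 1/alpha is the NB size. Because cells
// without the gRNA contribute a constant to the log-likelihood, restricting
// the fit to gRNA-carrying cells gives the same beta-hat and the same
// derivatives in beta as the all-cells fit with X*beta in the linear
// predictor.
//
// Log-likelihood (dropping beta-free terms):
//   l(beta)  = sum_i [ y_i log(mu_i) - (y_i + theta) log(mu_i + theta) ]
//   l'(beta) = sum_i theta (y_i - mu_i) / (mu_i + theta)
//   l''(beta)= -sum_i theta mu_i (y_i + theta) / (mu_i + theta)^2
//
// The z-value is beta-hat / SE with SE from the observed information -l''.

static const double BETA_CAP = 30.0;

static double nb_loglik(const std::vector<double>& y,
                        const std::vector<double>& o,
                        double theta, double beta) {
  double ll = 0.0;
  for (size_t i = 0; i < y.size(); ++i) {
    double eta = beta + o[i];
    double mu = std::exp(eta);
    ll += y[i] * eta - (y[i] + theta) * std::log(mu + theta);
  }
  return ll;
}

// Newton with step halving; returns (beta, z, converged).
static void fit_one(const std::vector<double>& y,
                    const std::vector<double>& o,
                    double theta,
                    double& beta_out, double& z_out, bool& conv_out) {
  size_t n = y.size();
  double sy = 0.0, se = 0.0;
  for (size_t i = 0; i < n; ++i) { sy += y[i]; se += std::exp(o[i]); }
  if (n == 0 || sy <= 0.0) {
    beta_out = NA_REAL; z_out = NA_REAL; conv_out = false;
    return;
  }
  // moment init: solve sum(mu_i) = sum(y_i)
  double beta = std::log(sy / se);
  if (beta > BETA_CAP) beta = BETA_CAP;
  if (beta < -BETA_CAP) beta = -BETA_CAP;

  bool converged = false;
  double info = 0.0;
  double ll = nb_loglik(y, o, theta, beta);
  for (int iter = 0; iter < 100; ++iter) {
    double score = 0.0;
    info = 0.0;
    for (size_t i = 0; i < n; ++i) {
      double mu = std::exp(beta + o[i]);
      double d = mu + theta;
      score += theta * (y[i] - mu) / d;
      info += theta * mu * (y[i] + theta) / (d * d);
    }
    if (info <= 0.0) break;
    double step = score / info;
    if (std::fabs(step) < 1e-12) { converged = true; break; }
    double beta_new = beta + step;
    if (beta_new > BETA_CAP) beta_new = BETA_CAP;
    if (beta_new < -BETA_CAP) beta_new = -BETA_CAP;
    double ll_new = nb_loglik(y, o, theta, beta_new);
    int halvings = 0;
    while (ll_new < ll && halvings < 30) {
      beta_new = (beta + beta_new) / 2.0;
      ll_new = nb_loglik(y, o, theta, beta_new);
      ++halvings;
    }
    if (std::fabs(beta_new - beta) < 1e-12) { beta = beta_new; converged = true; break; }
    beta = beta_new;
    ll = ll_new;
  }
  // observed information at the solution
  info = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double mu = std::exp(beta + o[i]);
    double d = mu + theta;
    info += theta * mu * (y[i] + theta) / (d * d);
  }
  beta_out = beta;
  z_out = (info > 0.0) ? beta * std::sqrt(info) : NA_REAL;
  conv_out = converged && info > 0.0;
}

// [[Rcpp::export]]
List distill_fit_cpp(NumericVector y, NumericVector offsets, double theta) {
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> ov(offsets.begin(), offsets.end());
  double beta, z; bool conv;
  fit_one(yv, ov, theta, beta, z, conv);
  return List::create(_["beta"] = beta, _["z"] = z, _["converged"] = conv);
}

// Scores B resamples: idx is a list of 1-based index vectors into y/offsets,
// one per resample (the cells drawn to carry the gRNA).
// [[Rcpp::export]]
NumericVector distill_scores_cpp(NumericVector y, NumericVector offsets,
                                 double theta, List idx) {
  int B = idx.size();
  NumericVector z(B);
  for (int b = 0; b < B; ++b) {
    IntegerVector ix = idx[b];
    size_t m = ix.size();
    std::vector<double> yv(m), ov(m);
    for (size_t j = 0; j < m; ++j) {
      yv[j] = y[ix[j] - 1];
      ov[j] = offsets[ix[j] - 1];
    }
    double beta, zz; bool conv;
    fit_one(yv, ov, theta, beta, zz, conv);
    z[b] = conv ? zz : NA_REAL;
  }
  return z;
}
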