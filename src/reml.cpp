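// Weighted linear mixed model with a single random intercept (subject),
// fitted by REML with the variance ratio theta = tau^2 / sigma^2 profiled
// out by one-dimensional search.
//
// Model: y = X beta + Z u + e,  u ~ N(0, tau^2 I_q),  e_j ~ N(0, sigma^2 / w_j)
// Marginal covariance (up to sigma^2): Sigma(theta) = W^{-1} + theta Z Z'.
// Z Z' is block-diagonal over subjects, so Sigma^{-1} follows from
// Sherman-Morrison within each subject block:
//   Sigma_i^{-1} = W_i - a_i (W_i 1)(W_i 1)',  a_i = theta / (1 + theta s_i),
//   s_i = sum of the subject's weights,
// and log|Sigma| = -sum(log w) + sum_i log(1 + theta s_i).
//
// Weights are normalized to mean 1 within each gene, making the fit
// invariant to rescaling all of a gene's weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct GenePre {
  // theta-independent pieces
  arma::mat A0;       // X' W X
  arma::vec b0;       // X' W y
  double yty0;        // y' W y
  double sumlogw;     // sum log w
  // per-group pieces
  arma::mat xw;       // p x q, column i = X_i' w_i
  arma::vec yw;       // q, y_i' w_i
  arma::vec s;        // q, sum of group weights
  int n, p, q;
};

// REML criterion (-2 restricted log-likelihood up to a constant) at theta;
// fills beta, Ainv, sigma2 as side effects.
double reml_crit(const GenePre &g, double theta,
                 arma::vec &beta, arma::mat &Ainv, double &sigma2) {
  arma::mat A = g.A0;
  arma::vec b = g.b0;
  double yty = g.yty0;
  double logdet = -g.sumlogw;
  for (int i = 0; i < g.q; ++i) {
    double a = theta / (1.0 + theta * g.s[i]);
    if (a != 0.0) {
      A -= a * (g.xw.col(i) * g.xw.col(i).t());
      b -= a * g.yw[i] * g.xw.col(i);
      yty -= a * g.yw[i] * g.yw[i];
    }
    logdet += std::log1p(theta * g.s[i]);
  }
  arma::mat As = arma::symmatu(A);
  bool ok = arma::inv_sympd(Ainv, As);
  if (!ok) {
    ok = arma::inv(Ainv, As);
    if (!ok) return std::numeric_limits<double>::infinity();
  }
  beta = Ainv * b;
  double rss = yty - arma::dot(beta, b);
  if (rss < 1e-300) rss = 1e-300;
  sigma2 = rss / (g.n - g.p);
  double ldA, sign;
  arma::log_det(ldA, sign, As);
  return (g.n - g.p) * std::log(sigma2) + logdet + ldA;
}

} // namespace

// [[Rcpp::export(name = ".reml_fit_matrix")]]
List reml_fit_matrix(const arma::mat &Y, const arma::mat &X,
                     const arma::mat &W, const IntegerVector &group,
                     double theta_max = 50.0) {
  const int G = Y.n_rows, n = Y.n_cols, p = X.n_cols;
  if ((int)W.n_rows != G || (int)W.n_cols != n)
    stop("weight matrix shape mismatch");
  if (group.size() != n) stop("group length mismatch");
  int q = 0;
  for (int j = 0; j < n; ++j) {
    if (group[j] < 0) stop("group indices must be 0-based non-negative");
    if (group[j] + 1 > q) q = group[j] + 1;
  }

  arma::mat beta_out(G, p, arma::fill::value(NA_REAL));
  arma::mat se_unit_out(G, p, arma::fill::value(NA_REAL));
  arma::vec sigma2_out(G, arma::fill::value(NA_REAL));
  arma::vec tau2_out(G, arma::fill::value(NA_REAL));
  LogicalVector converged(G, false);

  // theta search grid (log-spaced) shared across genes
  const int ngrid = 21;
  std::vector<double> grid(ngrid + 1);
  grid[0] = 0.0;
  for (int i = 0; i < ngrid; ++i)
    grid[i + 1] = std::exp(std::log(1e-4) +
                           i * (std::log(theta_max) - std::log(1e-4)) /
                               (ngrid - 1));

  GenePre g;
  g.n = n; g.p = p; g.q = q;
  arma::vec beta(p); arma::mat Ainv(p, p); double sigma2 = 0.0;

  for (int r = 0; r < G; ++r) {
    arma::rowvec yr = Y.row(r);
    arma::rowvec wr = W.row(r);
    double wmean = arma::mean(wr);
    if (!(wmean > 0)) continue;
    wr /= wmean; // scale invariance within gene

    // precompute theta-independent pieces
    g.A0.zeros(p, p); g.b0.zeros(p);
    g.yty0 = 0.0; g.sumlogw = 0.0;
    g.xw.zeros(p, q); g.yw.zeros(q); g.s.zeros(q);
    for (int j = 0; j < n; ++j) {
      double wj = wr[j];
      if (!(wj > 0) || !std::isfinite(yr[j])) { g.s.zeros(); break; }
      arma::vec xj = X.row(j).t();
      g.A0 += wj * (xj * xj.t());
      g.b0 += wj * yr[j] * xj;
      g.yty0 += wj * yr[j] * yr[j];
      g.sumlogw += std::log(wj);
      int gi = group[j];
      g.xw.col(gi) += wj * xj;
      g.yw[gi] += wj * yr[j];
      g.s[gi] += wj;
    }
    if (arma::accu(g.s) <= 0) continue;

    // coarse grid, then golden-section refinement around the best point
    int best = 0; double fbest = std::numeric_limits<double>::infinity();
    for (int i = 0; i <= ngrid; ++i) {
      double f = reml_crit(g, grid[i], beta, Ainv, sigma2);
      if (f < fbest) { fbest = f; best = i; }
    }
    double lo = grid[best > 0 ? best - 1 : 0];
    double hi = grid[best < ngrid ? best + 1 : ngrid];
    const double gr = 0.6180339887498949;
    double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
    double fc = reml_crit(g, c, beta, Ainv, sigma2);
    double fd = reml_crit(g, d, beta, Ainv, sigma2);
    for (int it = 0; it < 80 && (hi - lo) > 1e-9 * (1.0 + hi); ++it) {
      if (fc < fd) {
        hi = d; d = c; fd = fc;
        c = hi - gr * (hi - lo);
        fc = reml_crit(g, c, beta, Ainv, sigma2);
      } else {
        lo = c; c = d; fc = fd;
        d = lo + gr * (hi - lo);
        fd = reml_crit(g, d, beta, Ainv, sigma2);
      }
    }
    double theta_hat = (fc < fd) ? c : d;
    double f_hat = std::min(fc, fd);
    // boundary check against theta = 0 and the best grid point
    if (fbest < f_hat) { theta_hat = grid[best]; }
    double f0 = reml_crit(g, 0.0, beta, Ainv, sigma2);
    if (f0 <= std::min(f_hat, fbest)) theta_hat = 0.0;

    double f_final = reml_crit(g, theta_hat, beta, Ainv, sigma2);
    if (!std::isfinite(f_final)) continue;

    beta_out.row(r) = beta.t();
    se_unit_out.row(r) = arma::sqrt(Ainv.diag()).t();
    sigma2_out[r] = sigma2;
    tau2_out[r] = theta_hat * sigma2;
    converged[r] = true;
  }

  return List::create(
      _["beta"] = beta_out, _["se_unit"] = se_unit_out,
      _["sigma2"] = sigma2_out, _["tau2"] = tau2_out,
      _["df_resid"] = n - p - 1, _["converged"] = converged);
}
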