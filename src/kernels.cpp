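// MCMC kernels for the hierarchical spatial mixture model.
//
// All random numbers come from R's RNG (unif_rand/norm_rand/R::r*), so a
// set.seed() on the R side makes every kernel, and the full driver, exactly
// reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// ---------------------------------------------------------------------------
// small utilities
// ---------------------------------------------------------------------------

// N x C matrix of log N(x_i; mu_c, Sigma) densities
static arma::mat mvn_loglik(const arma::mat& X, const arma::mat& mu,
                            const arma::mat& Sigma) {
  const int N = X.n_rows, J = X.n_cols, C = mu.n_rows;
  arma::mat L = arma::chol(Sigma, "lower");
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  arma::mat out(N, C);
  for (int c = 0; c < C; ++c) {
    arma::mat D = X.each_row() - mu.row(c);            // N x J
    arma::mat V = arma::solve(arma::trimatl(L), D.t()); // J x N
    out.col(c) = -0.5 * (J * LOG2PI + logdet + arma::sum(V % V, 0).t());
  }
  return out;
}

// draw index in 0..(K-1) from unnormalized log weights
static int sample_log_weights(const arma::rowvec& lw) {
  arma::rowvec w = arma::exp(lw - lw.max());
  double tot = arma::accu(w), u = unif_rand() * tot, cum = 0.0;
  for (arma::uword k = 0; k < w.n_elem; ++k) {
    cum += w(k);
    if (u <= cum) return (int)k;
  }
  return (int)w.n_elem - 1;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  }
  void unite(int i, int j) {
    int ri = find(i), rj = find(j);
    if (ri != rj) parent[ri] = rj;
  }
};

// One Swendsen-Wang sweep on the node range [lo, hi] (0-based, inclusive) of
// z (0-based labels).  Bonds are placed on monochromatic edges with
// probability 1 - exp(-beta); each bond cluster then receives a common label
// r with probability proportional to prod_{i in cluster} exp(logw(i, r)).
// logw == nullptr means uniform label weights (plain Potts).
static void sw_sweep_range(std::vector<int>& z, const arma::imat& edges,
                           double beta, const arma::mat* logw,
                           int lo, int hi, int R) {
  const int n = hi - lo + 1;
  UnionFind uf(n);
  const double pbond = 1.0 - std::exp(-beta);
  for (arma::uword e = 0; e < edges.n_rows; ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    if (z[i] == z[j] && unif_rand() < pbond) uf.unite(i - lo, j - lo);
  }
  arma::mat A(R, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (logw) A.col(r) += logw->row(lo + i).t();
  }
  std::vector<int> lab(n, -1);
  for (int i = 0; i < n; ++i) {
    if (uf.find(i) == i) lab[i] = sample_log_weights(A.col(i).t());
  }
  for (int i = 0; i < n; ++i) z[lo + i] = lab[uf.find(i)];
}

static int count_mono(const std::vector<int>& z, const arma::imat& edges) {
  int s = 0;
  for (arma::uword e = 0; e < edges.n_rows; ++e)
    if (z[edges(e, 0)] == z[edges(e, 1)]) ++s;
  return s;
}

// Bartlett draw: W ~ Wishart(df, V), via lower Cholesky of V
static arma::mat rwishart(double df, const arma::mat& V) {
  const int p = V.n_rows;
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static double lmgamma(double a, int p) {
  double s = 0.25 * p * (p - 1) * std::log(M_PI);
  for (int i = 0; i < p; ++i) s += R::lgammafn(a - 0.5 * i);
  return s;
}

// ---------------------------------------------------------------------------
// exported kernels (thin R wrappers add validation)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_mvn_loglik(const arma::mat& X, const arma::mat& mu,
                         const arma::mat& Sigma) {
  return mvn_loglik(X, mu, Sigma);
}

// [[Rcpp::export]]
IntegerVector cpp_sample_c(const arma::mat& X, const IntegerVector& z,
                           const arma::mat& mu, const arma::mat& Sigma,
                           const arma::mat& logpi) {
  const int N = X.n_rows, C = mu.n_rows;
  arma::mat ll = mvn_loglik(X, mu, Sigma);
  IntegerVector c(N);
  for (int i = 0; i < N; ++i) {
    arma::rowvec lw(C);
    for (int k = 0; k < C; ++k) lw(k) = ll(i, k) + logpi(k, z[i] - 1);
    c[i] = sample_log_weights(lw) + 1;
  }
  return c;
}

// conjugate draws of mu (given lam) then lam (given new mu)
// [[Rcpp::export]]
List cpp_sample_mu_lam(const arma::mat& X, const IntegerVector& c, int C,
                       const arma::mat& Sigma, const arma::vec& m0,
                       const arma::vec& lam, double lam_shape,
                       double lam_rate) {
  const int N = X.n_rows, J = X.n_cols;
  arma::mat Sinv = arma::inv_sympd(Sigma);
  arma::mat mu(C, J);
  arma::vec nc(C, arma::fill::zeros);
  arma::mat sx(C, J, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    int k = c[i] - 1;
    nc(k) += 1.0;
    sx.row(k) += X.row(i);
  }
  for (int k = 0; k < C; ++k) {
    arma::mat P = arma::diagmat(1.0 / lam) + nc(k) * Sinv;
    arma::vec b = (m0 / lam) + Sinv * sx.row(k).t();
    arma::mat U = arma::chol(P);                // upper
    arma::vec mean = arma::solve(P, b);
    arma::vec zr(J);
    for (int j = 0; j < J; ++j) zr(j) = norm_rand();
    mu.row(k) = (mean + arma::solve(arma::trimatu(U), zr)).t();
  }
  arma::vec lam_new(J);
  for (int j = 0; j < J; ++j) {
    double ss = 0.0;
    for (int k = 0; k < C; ++k) ss += std::pow(mu(k, j) - m0(j), 2.0);
    double shape = lam_shape + 0.5 * C, rate = lam_rate + 0.5 * ss;
    lam_new(j) = rate / R::rgamma(shape, 1.0);   // inverse-gamma draw
  }
  return List::create(_["mu"] = mu, _["lam"] = lam_new);
}

// [[Rcpp::export]]
arma::mat cpp_sample_sigma(const arma::mat& X, const IntegerVector& c,
                           const arma::mat& mu, double w_df,
                           const arma::mat& W_scale) {
  const int N = X.n_rows, J = X.n_cols;
  arma::mat SS = W_scale;
  for (int i = 0; i < N; ++i) {
    arma::rowvec d = X.row(i) - mu.row(c[i] - 1);
    SS += d.t() * d;
  }
  arma::mat W = rwishart(w_df + N, arma::inv_sympd(SS));
  return arma::inv_sympd(W);
}

// [[Rcpp::export]]
arma::mat cpp_sample_pi(const IntegerVector& c, const IntegerVector& z, int C,
                        int R_dom, double alpha) {
  arma::mat cnt(C, R_dom, arma::fill::zeros);
  for (int i = 0; i < c.size(); ++i) cnt(c[i] - 1, z[i] - 1) += 1.0;
  arma::mat pi(C, R_dom);
  for (int r = 0; r < R_dom; ++r) {
    double tot = 0.0;
    for (int k = 0; k < C; ++k) {
      pi(k, r) = R::rgamma(alpha + cnt(k, r), 1.0);
      tot += pi(k, r);
    }
    pi.col(r) /= tot;
  }
  return pi;
}

// [[Rcpp::export]]
IntegerVector cpp_sw_sweep(const IntegerVector& z, const IntegerMatrix& edges,
                           double beta, const NumericMatrix& logw, int R_dom) {
  const int n = z.size();
  std::vector<int> zz(n);
  for (int i = 0; i < n; ++i) zz[i] = z[i] - 1;
  arma::imat E(edges.nrow(), 2);
  for (int e = 0; e < edges.nrow(); ++e) {
    E(e, 0) = edges(e, 0) - 1;
    E(e, 1) = edges(e, 1) - 1;
  }
  if (logw.nrow() == 0) {
    sw_sweep_range(zz, E, beta, nullptr, 0, n - 1, R_dom);
  } else {
    arma::mat W(logw.begin(), logw.nrow(), logw.ncol());
    sw_sweep_range(zz, E, beta, &W, 0, n - 1, R_dom);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = zz[i] + 1;
  return out;
}

// [[Rcpp::export]]
int cpp_count_mono(const IntegerVector& z, const IntegerMatrix& edges) {
  std::vector<int> zz(z.begin(), z.end());
  arma::imat E(edges.nrow(), 2);
  for (int e = 0; e < edges.nrow(); ++e) {
    E(e, 0) = edges(e, 0) - 1;
    E(e, 1) = edges(e, 1) - 1;
  }
  return count_mono(zz, E);
}

static double reflect(double x, double lo, double hi) {
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

// exchange-algorithm update of beta given the (fixed) domain labels of one
// section; auxiliary configuration from inner_sweeps SW sweeps at the
// proposed beta, warm-started at the current labels
static double sample_beta_core(std::vector<int>& z, const arma::imat& edges,
                               double beta, double beta_max, double prop_sd,
                               int inner_sweeps, int lo, int hi, int R_dom,
                               int* accepted) {
  double bp = reflect(beta + prop_sd * norm_rand(), 0.0, beta_max);
  std::vector<int> aux(z);
  for (int s = 0; s < inner_sweeps; ++s)
    sw_sweep_range(aux, edges, bp, nullptr, lo, hi, R_dom);
  double Sz = count_mono(z, edges), Sa = count_mono(aux, edges);
  double logA = (bp - beta) * Sz + (beta - bp) * Sa;
  if (std::log(unif_rand()) < logA) {
    if (accepted) *accepted = 1;
    return bp;
  }
  if (accepted) *accepted = 0;
  return beta;
}

// [[Rcpp::export]]
List cpp_sample_beta(const IntegerVector& z, const IntegerMatrix& edges,
                     double beta, double beta_max, double prop_sd,
                     int inner_sweeps, int R_dom) {
  const int n = z.size();
  std::vector<int> zz(n);
  for (int i = 0; i < n; ++i) zz[i] = z[i] - 1;
  arma::imat E(edges.nrow(), 2);
  for (int e = 0; e < edges.nrow(); ++e) {
    E(e, 0) = edges(e, 0) - 1;
    E(e, 1) = edges(e, 1) - 1;
  }
  int acc = 0;
  double b = sample_beta_core(zz, E, beta, beta_max, prop_sd, inner_sweeps, 0,
                              n - 1, R_dom, &acc);
  return List::create(_["beta"] = b, _["accepted"] = (bool)acc);
}

// unnormalized log joint; the Potts partition function is omitted
static double log_posterior(const arma::mat& X, const std::vector<int>& c0,
                            const std::vector<int>& z0, const arma::mat& mu,
                            const arma::mat& Sigma, const arma::vec& lam,
                            const arma::mat& pi,
                            const std::vector<arma::imat>& edges, double beta,
                            const arma::vec& m0, double lam_shape,
                            double lam_rate, double w_df,
                            const arma::mat& W_scale, double alpha) {
  const int N = X.n_rows, J = X.n_cols, C = mu.n_rows;
  arma::mat ll = mvn_loglik(X, mu, Sigma);
  double lp = 0.0;
  for (int i = 0; i < N; ++i)
    lp += ll(i, c0[i]) + std::log(pi(c0[i], z0[i]));
  for (size_t l = 0; l < edges.size(); ++l)
    lp += beta * count_mono(z0, edges[l]);
  for (int k = 0; k < C; ++k)
    for (int j = 0; j < J; ++j)
      lp += R::dnorm(mu(k, j), m0(j), std::sqrt(lam(j)), 1);
  for (int j = 0; j < J; ++j)
    lp += lam_shape * std::log(lam_rate) - R::lgammafn(lam_shape) -
          (lam_shape + 1.0) * std::log(lam(j)) - lam_rate / lam(j);
  double ldS, sgn, ldW;
  arma::log_det(ldS, sgn, Sigma);
  arma::log_det(ldW, sgn, W_scale);
  lp += 0.5 * w_df * ldW - 0.5 * w_df * J * std::log(2.0) -
        lmgamma(0.5 * w_df, J) - 0.5 * (w_df + J + 1.0) * ldS -
        0.5 * arma::trace(W_scale * arma::inv_sympd(Sigma));
  lp += (alpha - 1.0) * arma::accu(arma::log(pi));
  return lp;
}

// Full systematic-scan driver: c -> (mu, lam) -> Sigma -> pi -> z -> beta.
// Cells must be ordered by section; sec_start/sec_end are 1-based inclusive
// node ranges per section; edge lists are global 1-based indices.  beta is
// updated from the first section only.
// [[Rcpp::export]]
List cpp_run_mcmc(const arma::mat& X, const List& edges_by_section,
                  const IntegerVector& sec_start, const IntegerVector& sec_end,
                  const IntegerVector& c_init, const IntegerVector& z_init,
                  const arma::mat& mu_init, const arma::mat& Sigma_init,
                  const arma::vec& lam_init, const arma::mat& pi_init,
                  double beta_init, double beta_max, double dirichlet_alpha,
                  const arma::vec& m0, double lam_shape, double lam_rate,
                  double w_df, const arma::mat& W_scale, int n_iter,
                  int burn_in, int inner_sweeps, double beta_prop_sd,
                  bool update_beta) {
  const int N = X.n_rows, J = X.n_cols, C = mu_init.n_rows,
            R_dom = pi_init.n_cols, L = edges_by_section.size();
  std::vector<arma::imat> edges(L);
  for (int l = 0; l < L; ++l) {
    IntegerMatrix E = edges_by_section[l];
    edges[l].set_size(E.nrow(), 2);
    for (int e = 0; e < E.nrow(); ++e) {
      edges[l](e, 0) = E(e, 0) - 1;
      edges[l](e, 1) = E(e, 1) - 1;
    }
  }
  std::vector<int> c0(N), z0(N);
  for (int i = 0; i < N; ++i) {
    c0[i] = c_init[i] - 1;
    z0[i] = z_init[i] - 1;
  }
  arma::mat mu = mu_init, Sigma = Sigma_init, pi = pi_init;
  arma::vec lam = lam_init;
  double beta = beta_init;

  const int n_keep = n_iter - burn_in;
  IntegerMatrix c_draws(n_keep, N), z_draws(n_keep, N);
  arma::mat mu_draws(n_keep, C * J), pi_draws(n_keep, C * R_dom),
      lam_draws(n_keep, J), sigma_draws(n_keep, J * J);
  arma::vec beta_draws(n_keep), lp_draws(n_keep);
  int n_acc = 0, n_prop = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- c | . ---
    arma::mat logpi = arma::log(pi);
    arma::mat ll = mvn_loglik(X, mu, Sigma);
    for (int i = 0; i < N; ++i) {
      arma::rowvec lw(C);
      for (int k = 0; k < C; ++k) lw(k) = ll(i, k) + logpi(k, z0[i]);
      c0[i] = sample_log_weights(lw);
    }
    // --- mu, lam | . ---
    {
      arma::mat Sinv = arma::inv_sympd(Sigma);
      arma::vec nc(C, arma::fill::zeros);
      arma::mat sx(C, J, arma::fill::zeros);
      for (int i = 0; i < N; ++i) {
        nc(c0[i]) += 1.0;
        sx.row(c0[i]) += X.row(i);
      }
      for (int k = 0; k < C; ++k) {
        arma::mat P = arma::diagmat(1.0 / lam) + nc(k) * Sinv;
        arma::vec b = (m0 / lam) + Sinv * sx.row(k).t();
        arma::mat U = arma::chol(P);
        arma::vec mean = arma::solve(P, b);
        arma::vec zr(J);
        for (int j = 0; j < J; ++j) zr(j) = norm_rand();
        mu.row(k) = (mean + arma::solve(arma::trimatu(U), zr)).t();
      }
      for (int j = 0; j < J; ++j) {
        double ss = 0.0;
        for (int k = 0; k < C; ++k) ss += std::pow(mu(k, j) - m0(j), 2.0);
        lam(j) = (lam_rate + 0.5 * ss) / R::rgamma(lam_shape + 0.5 * C, 1.0);
      }
    }
    // --- Sigma | . ---
    {
      arma::mat SS = W_scale;
      for (int i = 0; i < N; ++i) {
        arma::rowvec d = X.row(i) - mu.row(c0[i]);
        SS += d.t() * d;
      }
      Sigma = arma::inv_sympd(rwishart(w_df + N, arma::inv_sympd(SS)));
    }
    // --- pi | . ---
    {
      arma::mat cnt(C, R_dom, arma::fill::zeros);
      for (int i = 0; i < N; ++i) cnt(c0[i], z0[i]) += 1.0;
      for (int r = 0; r < R_dom; ++r) {
        double tot = 0.0;
        for (int k = 0; k < C; ++k) {
          pi(k, r) = R::rgamma(dirichlet_alpha + cnt(k, r), 1.0);
          tot += pi(k, r);
        }
        pi.col(r) /= tot;
      }
    }
    // --- z | . (SW sweep per section) ---
    {
      arma::mat logpi2 = arma::log(pi);
      arma::mat logw(N, R_dom);
      for (int i = 0; i < N; ++i) logw.row(i) = logpi2.row(c0[i]);
      for (int l = 0; l < L; ++l)
        sw_sweep_range(z0, edges[l], beta, &logw, sec_start[l] - 1,
                       sec_end[l] - 1, R_dom);
    }
    // --- beta | z of section 1 ---
    if (update_beta) {
      int acc = 0;
      beta = sample_beta_core(z0, edges[0], beta, beta_max, beta_prop_sd,
                              inner_sweeps, sec_start[0] - 1, sec_end[0] - 1,
                              R_dom, &acc);
      n_acc += acc;
      ++n_prop;
    }
    if (it >= burn_in) {
      int d = it - burn_in;
      for (int i = 0; i < N; ++i) {
        c_draws(d, i) = c0[i] + 1;
        z_draws(d, i) = z0[i] + 1;
      }
      mu_draws.row(d) = arma::vectorise(mu).t();
      sigma_draws.row(d) = arma::vectorise(Sigma).t();
      pi_draws.row(d) = arma::vectorise(pi).t();
      lam_draws.row(d) = lam.t();
      beta_draws(d) = beta;
      lp_draws(d) = log_posterior(X, c0, z0, mu, Sigma, lam, pi, edges, beta,
                                  m0, lam_shape, lam_rate, w_df, W_scale,
                                  dirichlet_alpha);
    }
  }
  return List::create(
      _["c_draws"] = c_draws, _["z_draws"] = z_draws,
      _["mu_draws"] = mu_draws, _["pi_draws"] = pi_draws,
      _["lam_draws"] = lam_draws, _["sigma_draws"] = sigma_draws,
      _["beta_draws"] = beta_draws,
      _["log_post_draws"] = lp_draws,
      _["beta_accept_rate"] = n_prop > 0 ? (double)n_acc / n_prop : NA_REAL);
}
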