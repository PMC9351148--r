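# Geweke-style joint-correctness check: forward draws from the prior versus
# a successive-conditional chain through all five update kernels, on a
# 6-node path with C = 2, R = 2, J = 1. Matching moments of beta, pi_11, the
# monochromatic-edge count, and lambda indicate that the kernels target the
# model's joint distribution.
geweke_toy <- function(n_draws = 20000, seed = 2024) {
  g <- path_graph(6)
  C <- 2
  R <- 2
  n <- 6
  hy <- spadom::model_hyper(C = C, R = R, J = 1, beta_max = 4,
                            dirichlet_alpha = 1, mean_prior_location = 0,
                            lambda_shape = 3, lambda_rate = 2,
                            wishart_df = 6, wishart_scale = matrix(1))
  conf <- as.matrix(expand.grid(rep(list(seq_len(R)), n)))
  mono <- apply(conf, 1, function(z) {
    sum(z[g$edges[, 1]] == z[g$edges[, 2]])
  })
  rdirich <- function(a) {
    gg <- rgamma(length(a), a)
    gg / sum(gg)
  }
  draw_prior <- function() {
    beta <- runif(1, 0, hy$beta_max)
    w <- exp(beta * mono)
    z <- conf[sample.int(nrow(conf), 1, prob = w / sum(w)), ]
    pi <- cbind(rdirich(c(1, 1)), rdirich(c(1, 1)))
    cc <- vapply(z, function(r) sample.int(C, 1, prob = pi[, r]), integer(1))
    lam <- hy$lambda_rate / rgamma(1, hy$lambda_shape)
    mu <- matrix(rnorm(C, 0, sqrt(lam)), C, 1)
    sig2 <- hy$wishart_scale[1, 1] / rchisq(1, hy$wishart_df)
    list(beta = beta, z = as.integer(z), pi = pi, c = cc, lam = lam,
         mu = mu, Sigma = matrix(sig2))
  }
  stats_of <- function(st) {
    c(beta = st$beta, pi11 = st$pi[1, 1],
      mono = sum(st$z[g$edges[, 1]] == st$z[g$edges[, 2]]),
      lam = st$lam)
  }
  set.seed(seed)
  fwd <- t(replicate(n_draws, stats_of(draw_prior())))
  st <- draw_prior()
  succ <- matrix(0, n_draws, 4)
  for (d in seq_len(n_draws)) {
    x <- matrix(rnorm(n, st$mu[st$c, 1], sqrt(st$Sigma[1, 1])))
    f <- structure(x, section_of_cell = rep(1L, n),
                   class = c("spadom_features", "matrix", "array"))
    st$c <- spadom::sample_cell_labels(f, st)
    gp <- spadom::sample_gaussian_params(f, st$c, hy, st)
    st$mu <- gp$mu
    st$lam <- gp$lam
    st$Sigma <- gp$Sigma
    st$pi <- spadom::sample_compositions(st$c, st$z, hy)
    st$z <- spadom::sample_domain_labels_sw(st$c, st$z, g, st)
    st$beta <- spadom::sample_beta(st$z, g, st, hy, inner_sweeps = 20)$beta
    succ[d, ] <- stats_of(st)
  }
  zs <- vapply(1:4, function(k) {
    se_f <- sd(fwd[, k]) / sqrt(n_draws)
    se_s <- batch_se(succ[, k])
    (mean(fwd[, k]) - mean(succ[, k])) / sqrt(se_f^2 + se_s^2)
  }, numeric(1))
  names(zs) <- colnames(fwd)
  list(z_scores = zs, fwd = fwd, succ = succ)
}
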