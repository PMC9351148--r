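# conditional-distribution checks for the individual MCMC kernels

test_that("cell-type sampling respects zero prior mass and single-class limits", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1)
  f <- structure(x, section_of_cell = rep(1L, 30),
                 class = c("spadom_features", "matrix", "array"))
  # type 2 has zero mass in domain 1
  st <- list(z = rep(1L, 30), mu = matrix(c(0, 0), 2, 1), Sigma = matrix(1),
             pi = matrix(c(1, 0), 2, 1), beta = 0, lam = 1)
  for (r in 1:20) expect_true(all(sample_cell_labels(f, st) == 1L))
  st1 <- list(z = rep(1L, 30), mu = matrix(0, 1, 1), Sigma = matrix(1),
              pi = matrix(1, 1, 1), beta = 0, lam = 1)
  expect_true(all(sample_cell_labels(f, st1) == 1L))
})

test_that("two-class cell-type posteriors match the closed form", {
  # J = 1, two types, known parameters: exact posterior is a logistic form
  xs <- c(-1, 0.2, 0.5, 2)
  f <- structure(matrix(xs), section_of_cell = rep(1L, 4),
                 class = c("spadom_features", "matrix", "array"))
  mu <- matrix(c(0, 1), 2, 1)
  pivec <- c(0.3, 0.7)
  st <- list(z = rep(1L, 4), mu = mu, Sigma = matrix(1),
             pi = matrix(pivec, 2, 1), beta = 0, lam = 1)
  post1 <- pivec[1] * dnorm(xs, 0, 1) /
    (pivec[1] * dnorm(xs, 0, 1) + pivec[2] * dnorm(xs, 1, 1))
  set.seed(2)
  ndraw <- 10000
  hits <- numeric(4)
  for (d in seq_len(ndraw)) {
    hits <- hits + (sample_cell_labels(f, st) == 1L)
  }
  freq <- hits / ndraw
  se <- sqrt(post1 * (1 - post1) / ndraw)
  expect_true(all(abs(freq - post1) < 3 * se + 1e-9))
})

test_that("an empty cell type draws its mean from the prior", {
  set.seed(3)
  n <- 200
  x <- matrix(rnorm(n, 5, 1))
  f <- structure(x, section_of_cell = rep(1L, n),
                 class = c("spadom_features", "matrix", "array"))
  hy <- model_hyper(C = 2, R = 1, J = 1, mean_prior_location = 0,
                    lambda_shape = 2, lambda_rate = 1)
  st <- list(Sigma = matrix(1), lam = 1)
  draws <- replicate(2000, {
    sample_gaussian_params(f, rep(1L, n), hy, st)$mu[2, 1]
  })
  # mu_2 | lam = 1 ~ N(0, 1) exactly (no cells assigned to type 2)
  ks <- ks.test(draws, "pnorm", 0, 1)
  expect_gt(ks$p.value, 0.001)
})

test_that("posterior mean of an occupied type tracks its sample mean", {
  set.seed(4)
  n <- 2000
  x <- matrix(rnorm(n, 3, 1))
  f <- structure(x, section_of_cell = rep(1L, n),
                 class = c("spadom_features", "matrix", "array"))
  hy <- model_hyper(C = 1, R = 1, J = 1, mean_prior_location = 0)
  st <- list(Sigma = matrix(1), lam = 1)
  draws <- replicate(500, sample_gaussian_params(f, rep(1L, n), hy, st)$mu[1, 1])
  # closed-form conditional: precision 1 + n, mean n * xbar / (1 + n)
  exp_mean <- n * mean(x) / (1 + n)
  exp_sd <- sqrt(1 / (1 + n))
  expect_lt(abs(mean(draws) - exp_mean), 3 * exp_sd / sqrt(500) + 1e-9)
  expect_equal(sd(draws), exp_sd, tolerance = 0.2)
})

test_that("the covariance posterior concentrates around the truth", {
  set.seed(5)
  n <- 5000
  Sigma_true <- matrix(c(1, 0.4, 0.4, 0.8), 2, 2)
  x <- rmvn(n, c(0, 0), Sigma_true)
  f <- structure(x, section_of_cell = rep(1L, n),
                 class = c("spadom_features", "matrix", "array"))
  hy <- model_hyper(C = 1, R = 1, J = 2, mean_prior_location = c(0, 0))
  st <- list(Sigma = diag(2), lam = c(1, 1))
  acc <- matrix(0, 2, 2)
  ndraw <- 100
  for (d in seq_len(ndraw)) {
    # condition the mean at small prior scale so residuals are near-true
    g <- sample_gaussian_params(f, rep(1L, n), hy, st)
    acc <- acc + g$Sigma
  }
  expect_lt(norm(acc / ndraw - Sigma_true, "F"), 0.1)
})

test_that("composition draws follow the Dirichlet conditional", {
  hy <- model_hyper(C = 3, R = 1, J = 2, dirichlet_alpha = 1)
  cc <- rep(1:3, times = c(90, 5, 5))
  zz <- rep(1L, 100)
  set.seed(6)
  draws <- t(replicate(10000, as.numeric(sample_compositions(cc, zz, hy))))
  target <- c(91, 6, 6) / 103
  a0 <- 103
  vars <- target * (1 - target) / (a0 + 1)
  expect_true(all(abs(colMeans(draws) - target) <
                    3 * sqrt(vars / 10000) + 1e-9))
  expect_equal(apply(draws, 2, var), vars, tolerance = 0.1)

  # empty domain: prior draw with uniform mean
  hy2 <- model_hyper(C = 2, R = 2, J = 2, dirichlet_alpha = 1)
  set.seed(7)
  d2 <- replicate(4000, sample_compositions(c(1L, 2L), c(1L, 1L), hy2)[1, 2])
  expect_lt(abs(mean(d2) - 0.5), 3 * sqrt(1 / 12 / 4000))
})

test_that("domain sweep at beta = 0 draws independently from the compositions", {
  set.seed(8)
  g <- path_graph(4)
  pi <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)  # C = 2, R = 2
  st <- list(pi = pi, beta = 0)
  cc <- c(1L, 1L, 2L, 2L)
  ndraw <- 10000
  hits <- matrix(0, 4, 2)
  z <- rep(1L, 4)
  for (d in seq_len(ndraw)) {
    z <- sample_domain_labels_sw(cc, z, g, st)
    hits[cbind(1:4, z)] <- hits[cbind(1:4, z)] + 1
  }
  # marginal P(z_i = r) propto pi[c_i, r]
  probs <- t(apply(pi[cc, ], 1, function(w) w / sum(w)))
  freq <- hits / ndraw
  se <- sqrt(probs * (1 - probs) / ndraw)
  expect_true(all(abs(freq - probs) < 4 * se))
})

test_that("bond placement rate matches 1 - exp(-beta)", {
  # single-edge graph, both labels equal, uniform weights: after one sweep
  # the labels agree with probability p + (1 - p) / R, p = 1 - exp(-beta)
  set.seed(9)
  g <- path_graph(2)
  R <- 4
  beta <- 1
  st <- list(pi = matrix(0.25, 1, R), beta = beta)
  n <- 20000
  agree <- 0
  for (d in seq_len(n)) {
    z <- sample_domain_labels_sw(c(1L, 1L), c(2L, 2L), g, st)
    agree <- agree + (z[1] == z[2])
  }
  p <- 1 - exp(-beta)
  target <- p + (1 - p) / R
  expect_lt(abs(agree / n - target), 4 * sqrt(target * (1 - target) / n))
})

test_that("beta proposals are reflected into the prior support", {
  set.seed(10)
  g <- lattice_graph_t(8, 8)
  z <- sample(1:4, 64, replace = TRUE)
  hy <- model_hyper(C = 4, R = 4, J = 2, beta_max = 4)
  st <- list(beta = 3.9)
  for (d in 1:200) {
    res <- sample_beta(z, g, st, hy, inner_sweeps = 2, prop_sd = 3)
    expect_gte(res$beta, 0)
    expect_lte(res$beta, 4)
    st$beta <- res$beta
  }
})
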