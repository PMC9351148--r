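separable_fit <- function(n_per = 60, n_iter = 400, seed = 5) {
  # 2 types, 2 domains: left half of a strip is type 1 / domain 1, right
  # half type 2 / domain 2, means 10 sigma apart
  set.seed(seed)
  n <- 2 * n_per
  coords <- cbind(c(runif(n_per, 0, 1), runif(n_per, 2, 3)), runif(n, 0, 1))
  truth <- rep(1:2, each = n_per)
  x <- rmvn(n, c(0, 0), diag(2))
  x[truth == 2, ] <- x[truth == 2, ] + 10
  f <- structure(x, section_of_cell = rep(1L, n),
                 class = c("spadom_features", "matrix", "array"))
  g <- knn_graph(coords, k = 4)
  hy <- model_hyper(C = 2, R = 2, J = 2)
  samples <- run_mcmc(f, list(g), hy, n_iter = n_iter,
                      burn_in = n_iter / 2, seed = seed)
  list(samples = samples, truth = truth, features = f, graph = g, hyper = hy)
}

test_that("run_mcmc is bit-reproducible under a fixed seed", {
  sf1 <- separable_fit(n_per = 30, n_iter = 100, seed = 7)
  sf2 <- separable_fit(n_per = 30, n_iter = 100, seed = 7)
  expect_identical(sf1$samples$c_draws, sf2$samples$c_draws)
  expect_identical(sf1$samples$z_draws, sf2$samples$z_draws)
  expect_identical(sf1$samples$beta_draws, sf2$samples$beta_draws)
  expect_identical(sf1$samples$log_post_draws, sf2$samples$log_post_draws)
})

test_that("a separable fixture is recovered exactly and log posteriors are finite", {
  sf <- separable_fit()
  expect_true(all(is.finite(sf$samples$log_post_draws)))
  est <- summarize_posterior(relabel_ecr(sf$samples))
  expect_equal(ari(est$c_hat, sf$truth), 1)
  expect_equal(ari(est$z_hat, sf$truth), 1)
  # estimated composition close to the empirical one (the identity here)
  pc <- attr(match_labels(est$c_hat, sf$truth), "perm")
  pz <- attr(match_labels(est$z_hat, sf$truth), "perm")
  aligned <- est$pi_hat
  aligned[pc, ] <- aligned
  aligned[, pz] <- aligned
  expect_lt(max(abs(aligned - diag(2))), 0.05)
})

test_that("ECR maps permuted copies of one allocation onto the pivot", {
  set.seed(13)
  base_c <- sample(1:4, 120, replace = TRUE)
  base_z <- sample(1:3, 120, replace = TRUE)
  D <- 10
  c_draws <- t(replicate(D, sample(4)[base_c]))
  z_draws <- t(replicate(D, sample(3)[base_z]))
  smp <- fake_samples(c_draws, z_draws, C = 4, R = 3,
                      log_post = seq_len(D))
  rel <- relabel_ecr(smp)
  for (d in seq_len(D)) {
    expect_identical(rel$c_draws[d, ], rel$c_draws[1, ])
    expect_identical(rel$z_draws[d, ], rel$z_draws[1, ])
  }
  # per-draw agreement with the truth is unchanged by relabeling
  for (d in seq_len(D)) {
    expect_equal(ari(rel$c_draws[d, ], base_c), 1)
    expect_equal(ari(smp$c_draws[d, ], rel$c_draws[d, ]), 1)
  }
})

test_that("ECR leaves an already-aligned chain untouched", {
  c_draws <- matrix(rep(c(1L, 1L, 2L, 3L), 5), 5, 4, byrow = TRUE)
  smp <- fake_samples(c_draws, c_draws, C = 3, R = 3)
  rel <- relabel_ecr(smp)
  expect_identical(rel$c_draws, smp$c_draws)
  expect_identical(rel$z_draws, smp$z_draws)
  expect_equal(rel$pi_draws, smp$pi_draws)
})

test_that("posterior summaries follow their contracts", {
  # single draw: the summary is that draw
  c_draws <- matrix(c(1L, 2L, 2L), 1)
  z_draws <- matrix(c(2L, 2L, 1L), 1)
  smp <- fake_samples(c_draws, z_draws, C = 2, R = 2)
  est <- summarize_posterior(smp)
  expect_equal(est$c_hat, c(1L, 2L, 2L))
  expect_equal(est$z_hat, c(2L, 2L, 1L))
  expect_equal(colSums(est$pi_hat), c(1, 1), tolerance = 1e-10)
})

test_that("beta is recovered from a Potts configuration on a lattice", {
  # criterion-style parameter recovery: z ~ Potts(beta = 1) on 15 x 15
  set.seed(31)
  g <- lattice_graph_t(15, 15)
  R <- 4
  z <- sample.int(R, 225, replace = TRUE)
  st0 <- list(pi = matrix(1 / R, 1, R), beta = 1)
  for (s in 1:500) z <- sample_domain_labels_sw(rep(1L, 225), z, g, st0)
  hy <- model_hyper(C = 1, R = R, J = 2, beta_max = 4)
  st <- list(beta = 0.5)
  chain <- numeric(1500)
  for (d in seq_along(chain)) {
    res <- sample_beta(z, g, st, hy, inner_sweeps = 10, prop_sd = 0.1)
    st$beta <- res$beta
    chain[d] <- res$beta
  }
  expect_gt(mean(chain[501:1500]), 0.8)
  expect_lt(mean(chain[501:1500]), 1.2)
})

test_that("multi-section runs update beta from the first section only", {
  set.seed(17)
  g1 <- lattice_graph_t(6, 6)
  g2 <- lattice_graph_t(5, 5)
  z1 <- sample.int(3, 36, replace = TRUE)
  z2a <- sample.int(3, 25, replace = TRUE)
  z2b <- sample.int(3, 25, replace = TRUE)  # a different section-2 state
  hy <- model_hyper(C = 2, R = 3, J = 2)
  st <- list(beta = 1)
  set.seed(100)
  ra <- sample_beta(c(z1, z2a), list(g1, g2), st, hy)
  set.seed(100)
  rb <- sample_beta(c(z1, z2b), list(g1, g2), st, hy)
  expect_identical(ra, rb)
})

test_that("full-model recovery: compositions within RMSE 0.05 at 1000 cells", {
  set.seed(23)
  n <- 1000
  C <- 3
  R <- 3
  # moderate interaction: strong enough for coherent domains, below the
  # ordering transition of the degree-7 kNN graph (which collapses the
  # Potts draw onto a single domain)
  beta_true <- 0.5
  coords <- matrix(runif(2 * n), n, 2)
  g <- knn_graph(coords, k = 6)
  z <- sample.int(R, n, replace = TRUE)
  st0 <- list(pi = matrix(1 / R, 1, R), beta = beta_true)
  for (s in 1:300) z <- sample_domain_labels_sw(rep(1L, n), z, g, st0)
  pi_true <- matrix(c(0.7, 0.2, 0.1,
                      0.1, 0.8, 0.1,
                      0.25, 0.25, 0.5), C, R)
  cc <- vapply(z, function(r) sample.int(C, 1, prob = pi_true[, r]),
               integer(1))
  mu_true <- matrix(c(0, 0, 6, 0, 0, 6), C, 2, byrow = TRUE)
  x <- rmvn(n, c(0, 0), diag(2)) + mu_true[cc, ]
  f <- structure(x, section_of_cell = rep(1L, n),
                 class = c("spadom_features", "matrix", "array"))
  hy <- model_hyper(C = C, R = R, J = 2)
  smp <- run_mcmc(f, list(g), hy, n_iter = 2000, burn_in = 1000, seed = 23)
  est <- summarize_posterior(relabel_ecr(smp))
  pc <- attr(match_labels(est$c_hat, cc), "perm")
  pz <- attr(match_labels(est$z_hat, z), "perm")
  expect_lt(composition_rmse(est$pi_hat, pi_true, pc, pz), 0.05)
  # beta posterior is in a sane neighbourhood of the truth
  expect_lt(abs(mean(smp$beta_draws) - beta_true), 0.2)
})
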