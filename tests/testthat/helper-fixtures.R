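# shared fixtures and independent oracles used across the test files

# strip feature-matrix attributes for plain-matrix comparisons
unclass_f <- function(x) {
  attr(x, "section_of_cell") <- NULL
  class(x) <- NULL
  x
}

# multivariate normal draws (independent of the package's C++ path)
rmvn <- function(n, mu, Sigma) {
  J <- length(mu)
  matrix(stats::rnorm(n * J), n, J) %*% chol(Sigma) +
    matrix(mu, n, J, byrow = TRUE)
}

# two well-separated Gaussian blobs in feature space with section attribute
make_blobs <- function(n_per = 50, sep = 10, J = 2, seed = 42) {
  set.seed(seed)
  x <- rbind(rmvn(n_per, rep(0, J), diag(J)),
             rmvn(n_per, rep(sep, J), diag(J)))
  labels <- rep(1:2, each = n_per)
  feat <- spadom::extract_pcs(t(x), J = J)
  list(features = feat, labels = labels, raw = x)
}

# brute-force kNN edge union: the O(n^2) oracle for the graph builder
brute_knn_edges <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  edges <- NULL
  for (i in seq_len(n)) {
    o <- order(d[i, ], seq_len(n))
    o <- o[o != i][seq_len(k)]
    edges <- rbind(edges, cbind(pmin(i, o), pmax(i, o)))
  }
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# ARI straight from pair enumeration: O(n^2) textbook oracle
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# enumerate all Potts configurations of a small graph; returns configs and
# their exact probabilities
potts_enumeration <- function(graph, beta, R) {
  n <- graph$n_nodes
  conf <- as.matrix(expand.grid(rep(list(seq_len(R)), n)))
  pot <- apply(conf, 1, function(z) {
    sum(z[graph$edges[, 1]] == z[graph$edges[, 2]]) * beta
  })
  p <- exp(pot - max(pot))
  list(conf = conf, prob = p / sum(p))
}

# 4-neighbour lattice built independently of the package internals
lattice_graph_t <- function(nr, nc) {
  idx <- function(r, c) (c - 1L) * nr + r
  edges <- NULL
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (rr < nr) edges <- rbind(edges, c(idx(rr, cc), idx(rr + 1L, cc)))
      if (cc < nc) edges <- rbind(edges, c(idx(rr, cc), idx(rr, cc + 1L)))
    }
  }
  structure(list(n_nodes = nr * nc, edges = edges, section_id = 1L),
            class = "spadom_graph")
}

path_graph <- function(n) {
  structure(list(n_nodes = n,
                 edges = cbind(seq_len(n - 1), 2:n),
                 section_id = 1L),
            class = "spadom_graph")
}

# a minimal spadom_samples object for relabeling tests
fake_samples <- function(c_draws, z_draws, C, R, J = 2,
                         log_post = NULL) {
  D <- nrow(c_draws)
  if (is.null(log_post)) log_post <- rep(0, D)
  structure(list(
    c_draws = c_draws, z_draws = z_draws,
    mu_draws = matrix(rep(as.numeric(seq_len(C * J)), each = D), D),
    pi_draws = matrix(rep(as.numeric(seq_len(C * R)) / (C * R), each = D), D),
    lam_draws = matrix(1, D, J),
    sigma_draws = matrix(rep(as.numeric(diag(J)), each = D), D),
    beta_draws = rep(1, D), log_post_draws = log_post,
    beta_accept_rate = 0.5,
    hyper = spadom::model_hyper(C = C, R = R, J = J),
    n_iter = 2 * D, burn_in = D,
    section_sizes = ncol(c_draws)), class = "spadom_samples")
}

# batch-means standard error for autocorrelated chains
batch_se <- function(x, n_batch = 100) {
  m <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch), function(b) {
    mean(x[((b - 1) * m + 1):(b * m)])
  }, numeric(1))
  sd(means) / sqrt(n_batch)
}
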