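#' Hyperparameters of the hierarchical spatial mixture model
#'
#' The model assumes, for cell i with expression features `x_i` (J-vector):
#' \deqn{x_i | c_i = c ~ N(\mu_c, \Sigma)}
#' \deqn{c_i | z_i = r ~ Categorical(\pi_r)}
#' \deqn{z ~ Potts(V, \beta)}
#' with conjugate priors: `mu_{cj} | lambda_j ~ N(m_j, lambda_j)` with an
#' inverse-gamma prior on the feature scale `lambda_j` (a larger posterior
#' `lambda_j` marks a feature whose cell-type means are more spread out,
#' i.e. a more informative feature), an inverse-Wishart prior on the shared
#' covariance `Sigma`, a Dirichlet prior on each domain composition `pi_r`,
#' and a Uniform(0, `beta_max`) prior on the Potts interaction `beta`.
#'
#' @param C Number of cell types.
#' @param R Number of spatial domains.
#' @param J Feature dimension.
#' @param beta_max Upper bound of the uniform prior on beta (default 4).
#' @param dirichlet_alpha Dirichlet concentration for the compositions
#'   (default 1, flat).
#' @param mean_prior_location Length-J prior location of the cell-type means;
#'   defaults to the per-feature global mean at initialization.
#' @param lambda_shape,lambda_rate Inverse-gamma hyperparameters of the
#'   feature scales (defaults 2 and 1: prior mean 1, weakly informative).
#' @param wishart_df,wishart_scale Inverse-Wishart hyperparameters for Sigma
#'   (defaults J + 2 and the identity).
#' @return A `spadom_hyper` list.
#' @export
model_hyper <- function(C, R, J = 20, beta_max = 4, dirichlet_alpha = 1,
                        mean_prior_location = NULL, lambda_shape = 2,
                        lambda_rate = 1, wishart_df = J + 2,
                        wishart_scale = NULL) {
  stopifnot(C >= 1, R >= 1, J >= 1, beta_max > 0, dirichlet_alpha > 0,
            lambda_shape > 0, lambda_rate > 0, wishart_df > J - 1)
  if (is.null(wishart_scale)) wishart_scale <- diag(J)
  if (!is.null(mean_prior_location))
    stopifnot(length(mean_prior_location) == J)
  structure(list(C = as.integer(C), R = as.integer(R), J = as.integer(J),
                 beta_max = beta_max, dirichlet_alpha = dirichlet_alpha,
                 mean_prior_location = mean_prior_location,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate,
                 wishart_df = wishart_df, wishart_scale = wishart_scale),
            class = "spadom_hyper")
}

#' Validate a model state
#'
#' Checks the internal consistency of one MCMC configuration: label ranges,
#' column-stochastic composition matrix, positive-definite covariance, and
#' beta inside its prior support.
#'
#' @param state A `spadom_state` list with elements `c`, `z`, `mu` (C x J),
#'   `Sigma` (J x J), `lam` (J), `pi` (C x R), `beta`.
#' @param hyper A `spadom_hyper` object.
#' @return The state, invisibly; errors on violation.
#' @export
validate_state <- function(state, hyper) {
  stopifnot(all(state$c >= 1L), all(state$c <= hyper$C),
            all(state$z >= 1L), all(state$z <= hyper$R),
            all(dim(state$mu) == c(hyper$C, hyper$J)),
            all(dim(state$Sigma) == c(hyper$J, hyper$J)),
            length(state$lam) == hyper$J, all(state$lam > 0),
            all(dim(state$pi) == c(hyper$C, hyper$R)),
            state$beta >= 0, state$beta <= hyper$beta_max)
  if (max(abs(colSums(state$pi) - 1)) > 1e-10)
    stop("pi columns must sum to 1")
  ev <- eigen(state$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive-definite")
  invisible(state)
}

#' Gaussian log-likelihood of a cell's expression features
#'
#' `log N(x; mu_c, Sigma)` for one cell under a given cell type.
#'
#' @param x J-vector of expression features.
#' @param c Cell-type index.
#' @param state Model state (uses `mu` and `Sigma`).
#' @return Log density (scalar).
#' @export
loglik_cell <- function(x, c, state) {
  ev <- eigen(state$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("singular or non-positive-definite Sigma")
  drop(cpp_mvn_loglik(matrix(x, nrow = 1), state$mu, state$Sigma)[1, c])
}

#' Unnormalized Potts log-potential
#'
#' `beta` times the number of monochromatic edges of the graph: the log of
#' the Potts numerator.
#'
#' @param z Integer label vector on the graph's nodes.
#' @param graph A `spadom_graph`.
#' @param beta Interaction parameter.
#' @return Scalar.
#' @export
potts_log_potential <- function(z, graph, beta) {
  stopifnot(length(z) == graph$n_nodes)
  beta * cpp_count_mono(as.integer(z), graph$edges)
}

#' Exact Potts log partition function by enumeration
#'
#' Enumerates all `R^n` label configurations; used as a test oracle for the
#' doubly-intractable normalizing constant. Refuses graphs with more than 12
#' nodes.
#'
#' @param graph A `spadom_graph` with at most 12 nodes.
#' @param beta Interaction parameter.
#' @param R Number of labels.
#' @return `log C(beta)`, the log normalizing constant.
#' @export
potts_log_partition_exact <- function(graph, beta, R) {
  n <- graph$n_nodes
  if (n > 12) stop("exact partition function limited to graphs of <= 12 nodes")
  conf <- as.matrix(expand.grid(rep(list(seq_len(R)), n)))
  pots <- apply(conf, 1L, function(z) potts_log_potential(z, graph, beta))
  m <- max(pots)
  m + log(sum(exp(pots - m)))
}

#' Initialize the MCMC state
#'
#' Cell-type labels start at a k-means solution on the features; domain
#' labels at a k-means solution on neighbourhood-averaged features (each
#' cell's features averaged with its graph neighbours, which smooths
#' expression spatially). Means and covariance are set to the within-cluster
#' empirical moments, feature scales to their prior mean, compositions to the
#' smoothed empirical composition, and beta to 1.
#'
#' @param features `spadom_features` matrix.
#' @param graphs List of `spadom_graph`, one per section, in section order.
#' @param hyper `spadom_hyper`.
#' @return A `spadom_state` list.
#' @export
init_state <- function(features, graphs, hyper) {
  x <- unclass_features(features)
  sec <- attr(features, "section_of_cell")
  if (is.null(sec)) sec <- rep(1L, nrow(x))
  n <- nrow(x)
  C <- hyper$C
  R <- hyper$R

  cl <- kmeans_labels(x, C)
  # neighbourhood-averaged features for the domain-scale initialization
  xs <- x
  off <- 0L
  for (l in seq_along(graphs)) {
    idx <- which(sec == sort(unique(sec))[l])
    g <- graphs[[l]]
    deg <- rep(1, g$n_nodes)
    acc <- x[idx, , drop = FALSE]
    for (e in seq_len(nrow(g$edges))) {
      i <- g$edges[e, 1L]; j <- g$edges[e, 2L]
      acc[i, ] <- acc[i, ] + x[idx[j], ]
      acc[j, ] <- acc[j, ] + x[idx[i], ]
      deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1
    }
    xs[idx, ] <- acc / deg
    off <- off + g$n_nodes
  }
  zl <- kmeans_labels(xs, R)

  J <- ncol(x)
  mu <- matrix(0, C, J)
  for (k in seq_len(C)) {
    mu[k, ] <- if (any(cl == k)) colMeans(x[cl == k, , drop = FALSE])
               else colMeans(x)
  }
  resid <- x - mu[cl, , drop = FALSE]
  Sigma <- crossprod(resid) / max(1, n - C)
  Sigma <- Sigma + diag(1e-6 * mean(diag(Sigma)) + 1e-12, J)
  lam_mean <- if (hyper$lambda_shape > 1)
    hyper$lambda_rate / (hyper$lambda_shape - 1) else hyper$lambda_rate
  cnt <- table(factor(cl, levels = seq_len(C)), factor(zl, levels = seq_len(R)))
  pi <- sweep(unclass(cnt) + hyper$dirichlet_alpha, 2L,
              colSums(cnt) + C * hyper$dirichlet_alpha, "/")
  state <- list(c = cl, z = zl, mu = mu, Sigma = Sigma,
                lam = rep(lam_mean, J), pi = unname(pi), beta = 1.0)
  class(state) <- "spadom_state"
  validate_state(state, hyper)
  state
}

# k-means with empty-cluster protection: re-seed up to 10 times, then split
# off singletons for any cluster that stayed empty
kmeans_labels <- function(x, k) {
  if (k == 1L) return(rep(1L, nrow(x)))
  if (k >= nrow(x)) stop("more clusters than cells")
  for (attempt in seq_len(10L)) {
    km <- tryCatch(stats::kmeans(x, centers = k, nstart = 3, iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k)
      return(as.integer(km$cluster))
  }
  cl <- if (is.null(km)) rep(1L, nrow(x)) else as.integer(km$cluster)
  missing <- setdiff(seq_len(k), unique(cl))
  donors <- order(-tabulate(cl, k))
  for (m in missing) {
    big <- which(cl == donors[1L])
    cl[big[1L]] <- m
  }
  cl
}
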