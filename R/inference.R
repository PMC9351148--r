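#' Gibbs update of the cell-type labels
#'
#' Draws each cell's type independently given its domain label:
#' `p(c_i = c) propto N(x_i; mu_c, Sigma) * pi_{c, z_i}`, computed with a
#' log-sum-exp guard.
#'
#' @param features `spadom_features` matrix.
#' @param state Model state (uses `z`, `mu`, `Sigma`, `pi`).
#' @return Integer vector of new cell-type labels.
#' @export
sample_cell_labels <- function(features, state) {
  x <- unclass_features(features)
  as.integer(cpp_sample_c(x, as.integer(state$z), state$mu, state$Sigma,
                          log(state$pi)))
}

#' Conjugate updates of the Gaussian parameters
#'
#' Given the cell-type labels, draws the cell-type means from their
#' normal conditional (prior `N(m_j, lambda_j)` per coordinate), the feature
#' scales from their inverse-gamma conditional, and the shared covariance
#' from its inverse-Wishart conditional. Cell types with no assigned cells
#' receive prior draws.
#'
#' @param features `spadom_features` matrix.
#' @param c Integer cell-type labels.
#' @param hyper `spadom_hyper`.
#' @param state Current state; `Sigma` conditions the mean update and `lam`
#'   the prior scale.
#' @return List with `mu` (C x J), `lam` (length J), `Sigma` (J x J).
#' @export
sample_gaussian_params <- function(features, c, hyper, state) {
  x <- unclass_features(features)
  m0 <- prior_location(hyper, x)
  ml <- cpp_sample_mu_lam(x, as.integer(c), hyper$C, state$Sigma, m0,
                          state$lam, hyper$lambda_shape, hyper$lambda_rate)
  Sigma <- cpp_sample_sigma(x, as.integer(c), ml$mu, hyper$wishart_df,
                            hyper$wishart_scale)
  list(mu = ml$mu, lam = as.numeric(ml$lam), Sigma = Sigma)
}

prior_location <- function(hyper, x) {
  if (!is.null(hyper$mean_prior_location)) hyper$mean_prior_location
  else colMeans(x)
}

#' Gibbs update of the domain compositions
#'
#' Each domain's composition is drawn from
#' `Dirichlet(alpha + n_{.r})` where `n_{cr}` counts cells of type c in
#' domain r; an empty domain receives a prior draw.
#'
#' @param c,z Integer label vectors.
#' @param hyper `spadom_hyper`.
#' @return C x R column-stochastic matrix.
#' @export
sample_compositions <- function(c, z, hyper) {
  cpp_sample_pi(as.integer(c), as.integer(z), hyper$C, hyper$R,
                hyper$dirichlet_alpha)
}

#' Swendsen-Wang update of the domain labels
#'
#' One cluster sweep per section: bonds are placed on monochromatic edges
#' with probability `1 - exp(-beta)`, and each bond cluster draws a common
#' domain label r with probability proportional to
#' `prod_{i in cluster} pi_{c_i, r}`. At `beta = 0` this reduces to
#' independent draws from the composition columns.
#'
#' @param c Integer cell-type labels.
#' @param z Integer domain labels.
#' @param graphs A `spadom_graph` or list of them (one per section, node
#'   ranges contiguous in `z`).
#' @param state Model state (uses `pi`, `beta`).
#' @return Integer vector of new domain labels.
#' @export
sample_domain_labels_sw <- function(c, z, graphs, state) {
  if (inherits(graphs, "spadom_graph")) graphs <- list(graphs)
  logpi <- log(state$pi)
  logw <- logpi[c, , drop = FALSE]
  z <- as.integer(z)
  off <- 0L
  for (g in graphs) {
    idx <- off + seq_len(g$n_nodes)
    z[idx] <- cpp_sw_sweep(z[idx], g$edges, state$beta,
                           logw[idx, , drop = FALSE], ncol(state$pi))
    off <- off + g$n_nodes
  }
  z
}

#' Exchange-algorithm update of the Potts interaction parameter
#'
#' The posterior of beta involves the intractable Potts partition function.
#' A Gaussian random-walk proposal (reflected into `[0, beta_max]`) is
#' accepted with the exchange-algorithm ratio, which replaces the partition
#' function ratio with the monochromatic-edge statistic of an auxiliary
#' configuration simulated at the proposed beta (`inner_sweeps`
#' Swendsen-Wang sweeps warm-started at the current labels). With multiple
#' sections, only the first section's labels and graph are used.
#'
#' @param z Integer domain labels (all sections, section 1 first).
#' @param graphs A `spadom_graph` or list of them.
#' @param state Model state (uses `beta`).
#' @param hyper `spadom_hyper` (uses `beta_max`, `R`).
#' @param inner_sweeps Auxiliary SW sweeps (default 10).
#' @param prop_sd Random-walk standard deviation (default 0.1).
#' @return List with `beta` and logical `accepted`.
#' @export
sample_beta <- function(z, graphs, state, hyper, inner_sweeps = 10,
                        prop_sd = 0.1) {
  if (inherits(graphs, "spadom_graph")) graphs <- list(graphs)
  g1 <- graphs[[1L]]
  z1 <- as.integer(z[seq_len(g1$n_nodes)])
  res <- cpp_sample_beta(z1, g1$edges, state$beta, hyper$beta_max, prop_sd,
                         as.integer(inner_sweeps), hyper$R)
  list(beta = res$beta, accepted = res$accepted)
}

#' Run the full MCMC sampler
#'
#' Systematic-scan Gibbs/Metropolis sampler: cell-type labels, then Gaussian
#' parameters (means, feature scales, covariance), then compositions, then a
#' Swendsen-Wang domain sweep per section, then the exchange update of beta
#' (from the first section only). Draws after `burn_in` are stored. The same
#' seed reproduces the draws exactly.
#'
#' @param features `spadom_features` matrix, cells ordered by section.
#' @param graphs List of `spadom_graph` per section.
#' @param hyper `spadom_hyper`.
#' @param n_iter Total iterations (default 10000).
#' @param burn_in Discarded iterations (default `n_iter / 2`).
#' @param seed Optional integer seed.
#' @param init Optional initial state; defaults to [init_state()].
#' @param inner_sweeps,beta_prop_sd Exchange-update controls.
#' @param update_beta Set `FALSE` to hold beta fixed at its initial value.
#' @return A `spadom_samples` object with matrices `c_draws`, `z_draws`
#'   (draws x cells), `mu_draws` (draws x C*J), `pi_draws` (draws x C*R),
#'   `lam_draws`, `beta_draws`, `log_post_draws` (unnormalized joint with the
#'   Potts partition term omitted), and the beta acceptance rate.
#' @export
run_mcmc <- function(features, graphs, hyper, n_iter = 10000,
                     burn_in = n_iter / 2, seed = NULL, init = NULL,
                     inner_sweeps = 10, beta_prop_sd = 0.1,
                     update_beta = TRUE) {
  stopifnot(n_iter > burn_in, burn_in >= 0)
  if (inherits(graphs, "spadom_graph")) graphs <- list(graphs)
  if (!is.null(seed)) set.seed(seed)
  x <- unclass_features(features)
  sec <- attr(features, "section_of_cell")
  if (is.null(sec)) sec <- rep(1L, nrow(x))
  if (is.unsorted(sec)) stop("cells must be ordered by section")
  n_per <- vapply(graphs, function(g) g$n_nodes, integer(1))
  if (sum(n_per) != nrow(x))
    stop("graph node counts do not match the number of cells")
  sec_end <- cumsum(n_per)
  sec_start <- sec_end - n_per + 1L
  edges_global <- lapply(seq_along(graphs), function(l) {
    graphs[[l]]$edges + (sec_start[l] - 1L)
  })
  if (is.null(init)) init <- init_state(features, graphs, hyper)
  validate_state(init, hyper)
  m0 <- prior_location(hyper, x)

  raw <- cpp_run_mcmc(x, edges_global, as.integer(sec_start),
                      as.integer(sec_end), as.integer(init$c),
                      as.integer(init$z), init$mu, init$Sigma, init$lam,
                      init$pi, init$beta, hyper$beta_max,
                      hyper$dirichlet_alpha, m0, hyper$lambda_shape,
                      hyper$lambda_rate, hyper$wishart_df,
                      hyper$wishart_scale, as.integer(n_iter),
                      as.integer(burn_in), as.integer(inner_sweeps),
                      beta_prop_sd, isTRUE(update_beta))
  if (any(!is.finite(raw$log_post_draws)))
    stop("non-finite log-posterior encountered at stored draw(s) ",
         paste(utils::head(which(!is.finite(raw$log_post_draws)), 5),
               collapse = ", "),
         "; check for degenerate features (constant columns, huge scales)",
         call. = FALSE)
  structure(list(c_draws = raw$c_draws, z_draws = raw$z_draws,
                 mu_draws = raw$mu_draws, pi_draws = raw$pi_draws,
                 lam_draws = raw$lam_draws, sigma_draws = raw$sigma_draws,
                 beta_draws = as.numeric(raw$beta_draws),
                 log_post_draws = as.numeric(raw$log_post_draws),
                 beta_accept_rate = raw$beta_accept_rate,
                 hyper = hyper, n_iter = n_iter, burn_in = burn_in,
                 section_sizes = n_per),
            class = "spadom_samples")
}

#' @export
#' @method print spadom_samples
print.spadom_samples <- function(x, ...) {
  cat(sprintf(paste0("MCMC samples: %d draws (of %d iterations, %d burn-in), ",
                     "%d cells, C = %d, R = %d\n"),
              nrow(x$c_draws), x$n_iter, x$burn_in, ncol(x$c_draws),
              x$hyper$C, x$hyper$R))
  cat(sprintf("beta acceptance rate: %.2f\n", x$beta_accept_rate))
  invisible(x)
}

#' Relabel MCMC draws (iterative ECR)
#'
#' Mixture posteriors are invariant to label permutations, so raw draws of
#' the cell-type and domain allocations cannot be summarized directly. This
#' applies the iterative equivalence-class-representation scheme to the
#' cell-type chain and the domain chain independently: the pivot starts at
#' the draw with the highest stored log-posterior; each draw is mapped onto
#' the pivot by the permutation maximizing contingency-table agreement
#' (optimal assignment); the permutation is applied consistently to the
#' labels, to the mu/pi rows (cell types) and pi columns (domains); the pivot
#' is then updated to the per-cell modal allocation and the procedure
#' iterates until the total disagreement stops decreasing (at most
#' `max_iter` rounds).
#'
#' @param samples A `spadom_samples` object.
#' @param max_iter Maximum relabeling rounds (default 100).
#' @return The relabeled `spadom_samples`.
#' @export
relabel_ecr <- function(samples, max_iter = 100) {
  stopifnot(inherits(samples, "spadom_samples"))
  C <- samples$hyper$C
  R <- samples$hyper$R
  J <- samples$hyper$J
  pivot0 <- which.max(samples$log_post_draws)

  res_c <- ecr_chain(samples$c_draws, C, pivot0, max_iter)
  samples$c_draws <- res_c$labels
  for (d in seq_len(nrow(samples$c_draws))) {
    perm <- res_c$perms[d, ]
    mu <- matrix(samples$mu_draws[d, ], C, J)
    pi <- matrix(samples$pi_draws[d, ], C, R)
    mu[perm, ] <- mu
    pi[perm, ] <- pi
    samples$mu_draws[d, ] <- as.vector(mu)
    samples$pi_draws[d, ] <- as.vector(pi)
  }
  res_z <- ecr_chain(samples$z_draws, R, pivot0, max_iter)
  samples$z_draws <- res_z$labels
  for (d in seq_len(nrow(samples$z_draws))) {
    perm <- res_z$perms[d, ]
    pi <- matrix(samples$pi_draws[d, ], C, R)
    pi[, perm] <- pi
    samples$pi_draws[d, ] <- as.vector(pi)
  }
  samples
}

# iterative ECR on one allocation chain; returns relabeled draws and the
# total permutation applied to each draw
ecr_chain <- function(draws, K, pivot_draw, max_iter) {
  D <- nrow(draws)
  n <- ncol(draws)
  perms <- matrix(rep(seq_len(K), each = D), D, K)
  pivot <- draws[pivot_draw, ]
  prev_dis <- Inf
  for (iter in seq_len(max_iter)) {
    dis <- 0
    for (d in seq_len(D)) {
      sigma <- best_label_permutation(draws[d, ], pivot, K)
      if (any(sigma != seq_len(K))) {
        draws[d, ] <- sigma[draws[d, ]]
        perms[d, ] <- sigma[perms[d, ]]
      }
      dis <- dis + sum(draws[d, ] != pivot)
    }
    if (dis >= prev_dis) break
    prev_dis <- dis
    pivot <- apply_mode(draws, K)
  }
  list(labels = draws, perms = perms)
}

# per-cell marginal posterior mode; ties go to the smaller label
apply_mode <- function(draws, K) {
  apply(draws, 2L, function(col) which.max(tabulate(col, K)))
}

#' Posterior point estimates from relabeled draws
#'
#' Cell-type and domain labels are the per-cell marginal posterior modes
#' (ties to the smaller label); compositions are the posterior mean with
#' columns renormalized; beta, the feature scales and the cell-type means
#' are posterior means.
#'
#' @param samples A (relabeled) `spadom_samples` object.
#' @return List with `c_hat`, `z_hat`, `pi_hat`, `beta_hat`, `lam_hat`,
#'   `mu_hat`.
#' @export
summarize_posterior <- function(samples) {
  stopifnot(inherits(samples, "spadom_samples"))
  C <- samples$hyper$C
  R <- samples$hyper$R
  J <- samples$hyper$J
  pi_hat <- matrix(colMeans(samples$pi_draws), C, R)
  pi_hat <- sweep(pi_hat, 2L, colSums(pi_hat), "/")
  list(c_hat = apply_mode(samples$c_draws, C),
       z_hat = apply_mode(samples$z_draws, R),
       pi_hat = pi_hat,
       beta_hat = mean(samples$beta_draws),
       lam_hat = colMeans(samples$lam_draws),
       mu_hat = matrix(colMeans(samples$mu_draws), C, J),
       Sigma_hat = matrix(colMeans(samples$sigma_draws), J, J))
}
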