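#' Fit the joint cell-type / spatial-domain model
#'
#' Fits a Bayesian hierarchical model to single-cell resolution spatial
#' transcriptomic data that simultaneously clusters cells into `C` cell
#' types and segments the tissue into `R` spatial domains, each domain
#' characterized by its own cell-type composition. Expression enters through
#' the top `J` principal components of the library-size-normalized,
#' log-transformed counts; spatial structure enters through a Potts model on
#' the per-section k-nearest-neighbour graph whose interaction strength is
#' inferred from the data. Multiple sections are fitted jointly (shared cell
#' types, covariance and compositions; the interaction parameter is updated
#' from the first section).
#'
#' @param counts Non-negative count matrix, genes x cells. A `spadom_sim`
#'   object may be passed instead, in which case `coords` and `section` are
#'   taken from it.
#' @param coords Cells x 2 coordinate matrix.
#' @param section Optional integer section index per cell (default: one
#'   section).
#' @param C Number of cell types.
#' @param R Number of spatial domains.
#' @param J Number of expression features (default 20).
#' @param k Spatial neighbours per cell (default 6).
#' @param n_iter,burn_in MCMC iterations and burn-in (defaults 10000 / half).
#' @param beta_max Upper bound of the uniform prior on the Potts interaction
#'   (default 4).
#' @param alignment Cross-section alignment: `"standardize"`, `"none"` or
#'   `"external"`; default standardizes when there are multiple sections.
#' @param align_fun Alignment function when `alignment = "external"`.
#' @param target_sum Library-size normalization target (default: median
#'   library size).
#' @param hyper Optional `spadom_hyper` overriding the defaults.
#' @param seed Optional integer seed; fixes the full fit.
#' @param inner_sweeps,beta_prop_sd Exchange-update controls for beta.
#' @return A `spadom_fit` with elements `c` (cell types), `z` (domains),
#'   `pi` (C x R composition), `beta`, `lam`, `mu`, `Sigma`, the relabeled
#'   `samples`, and the inputs needed by the methods.
#' @seealso [simulate_experiment()] to generate synthetic data,
#'   [run_pipeline()] for a file-driven run.
#' @examples
#' sim <- simulate_experiment(sim_config(scenario = "I",
#'                                       n_cells_per_section = 150,
#'                                       n_genes = 50, seed = 1))
#' fit <- spadom(sim, C = 4, R = 4, J = 10, n_iter = 200, burn_in = 100,
#'               seed = 1)
#' fit
#' ari(fit$z, sim$true_z)
#' @export
spadom <- function(counts, coords = NULL, section = NULL, C, R, J = 20,
                   k = 6, n_iter = 10000, burn_in = n_iter / 2,
                   beta_max = 4, alignment = NULL, align_fun = NULL,
                   target_sum = NULL, hyper = NULL, seed = NULL,
                   inner_sweeps = 10, beta_prop_sd = 0.1) {
  cl <- match.call()
  if (inherits(counts, "spadom_sim")) {
    coords <- counts$coords
    section <- counts$section_of_cell
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  n <- ncol(counts)
  if (is.null(coords) || nrow(coords) != n)
    stop("coords must have one row per cell")
  if (is.null(section)) section <- rep(1L, n)
  o <- order(section)
  counts <- counts[, o, drop = FALSE]
  coords <- coords[o, , drop = FALSE]
  section <- section[o]
  L <- length(unique(section))
  if (is.null(alignment)) alignment <- if (L > 1L) "standardize" else "none"
  if (!is.null(seed)) set.seed(seed)

  norm <- normalize_log_counts(counts, target_sum = target_sum)
  features <- extract_pcs(norm, J = J, section_of_cell = section)
  J <- ncol(features)  # may have been reduced to rank
  features <- align_sections(features, method = alignment, fun = align_fun)
  graphs <- lapply(sort(unique(section)), function(l) {
    knn_graph(coords[section == l, , drop = FALSE], k = k, section_id = l)
  })
  if (is.null(hyper))
    hyper <- model_hyper(C = C, R = R, J = J, beta_max = beta_max)
  samples <- run_mcmc(features, graphs, hyper, n_iter = n_iter,
                      burn_in = burn_in, inner_sweeps = inner_sweeps,
                      beta_prop_sd = beta_prop_sd)
  samples <- relabel_ecr(samples)
  est <- summarize_posterior(samples)

  structure(list(c = est$c_hat, z = est$z_hat, pi = est$pi_hat,
                 beta = est$beta_hat, lam = est$lam_hat, mu = est$mu_hat,
                 Sigma = est$Sigma_hat, samples = samples,
                 features = features, coords = coords, section = section,
                 order = o, C = hyper$C, R = hyper$R, hyper = hyper,
                 seed = seed, call = cl),
            class = "spadom_fit")
}

#' @export
#' @method print spadom_fit
print.spadom_fit <- function(x, ...) {
  cat("Joint cell-type / spatial-domain fit\n")
  cat(sprintf("  %d cells, %d section(s), %d features\n",
              length(x$c), length(unique(x$section)), ncol(x$features)))
  cat(sprintf("  C = %d cell types, R = %d spatial domains\n", x$C, x$R))
  cat(sprintf("  Potts interaction beta = %.3f (acceptance %.2f)\n",
              x$beta, x$samples$beta_accept_rate))
  cat("  domain sizes:",
      paste(tabulate(x$z, x$R), collapse = " "), "\n")
  cat("  cell type sizes:",
      paste(tabulate(x$c, x$C), collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @method summary spadom_fit
summary.spadom_fit <- function(object, ...) {
  pi <- object$pi
  dimnames(pi) <- list(sprintf("type%d", seq_len(nrow(pi))),
                       sprintf("domain%d", seq_len(ncol(pi))))
  out <- list(pi = pi, beta = object$beta,
              beta_ci = stats::quantile(object$samples$beta_draws,
                                        c(0.025, 0.975)),
              lam = object$lam,
              domain_sizes = tabulate(object$z, object$R),
              type_sizes = tabulate(object$c, object$C),
              n_draws = length(object$samples$beta_draws))
  class(out) <- "summary.spadom_fit"
  out
}

#' @export
#' @method print summary.spadom_fit
print.summary.spadom_fit <- function(x, digits = 3, ...) {
  cat("Cell type composition by spatial domain (posterior mean):\n")
  print(round(x$pi, digits))
  cat(sprintf("\nPotts interaction beta: %.3f (95%% CI %.3f - %.3f), %d draws\n",
              x$beta, x$beta_ci[1], x$beta_ci[2], x$n_draws))
  cat("Feature scales lambda (larger = more type-informative feature):\n")
  print(round(x$lam, digits))
  invisible(x)
}

#' @export
coef.spadom_fit <- function(object,
                            what = c("pi", "beta", "lam", "mu"), ...) {
  what <- match.arg(what)
  object[[what]]
}

#' Spatial map of the fitted labels
#'
#' Scatter plot of the cells at their tissue coordinates, coloured by the
#' inferred spatial domain (default) or cell type, one panel per section.
#'
#' @param x A `spadom_fit`.
#' @param which `"domain"` or `"type"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spadom_fit <- function(x, which = c("domain", "type"), ...) {
  which <- match.arg(which)
  lab <- if (which == "domain") x$z else x$c
  secs <- sort(unique(x$section))
  op <- graphics::par(mfrow = c(1, length(secs)))
  on.exit(graphics::par(op))
  for (l in secs) {
    idx <- x$section == l
    graphics::plot(x$coords[idx, 1L], x$coords[idx, 2L],
                   col = lab[idx], pch = 16, cex = 0.5,
                   xlab = "x", ylab = "y",
                   main = sprintf("section %s (%s)", l, which), ...)
  }
  invisible(x)
}

#' @export
residuals.spadom_fit <- function(object, ...) {
  unclass_features(object$features) - object$mu[object$c, , drop = FALSE]
}

#' Simulate expression features from the fitted model
#'
#' Conditional on the inferred domain labels, draws cell types from the
#' fitted compositions and expression features from the fitted Gaussian
#' emission — a posterior-predictive check at the feature level.
#'
#' @param object A `spadom_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` lists with elements `c` and `features`.
#' @export
simulate.spadom_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$z)
  lapply(seq_len(nsim), function(s) {
    cc <- vapply(object$z, function(r) {
      sample.int(object$C, 1L, prob = object$pi[, r])
    }, integer(1))
    eps <- matrix(stats::rnorm(n * ncol(object$mu)), n) %*%
      chol(object$Sigma)
    list(c = cc, features = object$mu[cc, , drop = FALSE] + eps)
  })
}
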