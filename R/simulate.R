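#' Configuration for a synthetic layered-tissue experiment
#'
#' Defaults reproduce the baseline study conditions: 200 genes, DE
#' probability 0.2, DE log-location 1.1 (a three-fold median change),
#' roughly 1127 cells per section in a 5000 x 1000 rectangle split into four
#' vertical-band domains, with boundary shifts of up to 10% of the tissue
#' width on additional sections. Base expression parameters (gamma gene
#' means, log-normal library sizes, BCV overdispersion) are generic
#' smFISH-scale defaults.
#'
#' @param scenario Cell-type composition scenario: `"I"` one type per domain;
#'   `"II"` dominant type 90%, two others 5% each; `"III"` 50/25/25;
#'   `"IV"` equal thirds. Each domain misses a different type in II-IV.
#' @param n_genes,de_prob,de_facloc,de_facscale Splat-style DE controls:
#'   number of genes, per-(gene, type) DE probability, log-normal location
#'   and scale of the DE factors.
#' @param n_cells_per_section,n_sections,boundary_shift_fraction Layout
#'   controls.
#' @param rare_config Optional list from [rare_config()] replacing the
#'   scenario composition with a major + rare cell-type design.
#' @param genes_retained Optional number of genes kept after random gene
#'   exclusion.
#' @param mean_shape,mean_rate Gamma distribution of base gene means.
#' @param lib_loc,lib_scale Log-normal library sizes.
#' @param bcv_common,bcv_df Biological coefficient of variation controls.
#' @param width,height Tissue rectangle (arbitrary units).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `spadom_sim_config` list.
#' @export
sim_config <- function(scenario = c("I", "II", "III", "IV"), n_genes = 200,
                       de_prob = 0.2, de_facloc = 1.1, de_facscale = 0.4,
                       n_cells_per_section = 1127, n_sections = 1,
                       boundary_shift_fraction = 0.10, rare_config = NULL,
                       genes_retained = NULL, mean_shape = 0.6,
                       mean_rate = 0.3, lib_loc = log(1500),
                       lib_scale = 0.25, bcv_common = 0.2, bcv_df = 60,
                       width = 5000, height = 1000, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(de_prob >= 0, de_prob <= 1, de_facloc > 0, n_sections >= 1,
            n_genes >= 1, boundary_shift_fraction >= 0,
            boundary_shift_fraction <= 1)
  structure(as.list(environment()), class = "spadom_sim_config")
}

#' Rare cell-type configuration
#'
#' Four major types carry `major_fraction` (default 70%) of the cells with a
#' 2:1:1 within-domain composition; `n_rare` rare types split the remainder
#' equally, either spread uniformly over the tissue (`"random"`) or each
#' confined to a single domain (`"domain_specific"`).
#'
#' @param n_rare Number of rare types (6 or 10 in the study design; other
#'   values proceed with a warning).
#' @param major_fraction Fraction of cells in major types (default 0.70).
#' @param rare_pattern `"random"` or `"domain_specific"`.
#' @export
rare_config <- function(n_rare = 6, major_fraction = 0.70,
                        rare_pattern = c("random", "domain_specific")) {
  rare_pattern <- match.arg(rare_pattern)
  if (!n_rare %in% c(6L, 10L))
    warning("n_rare outside the study design {6, 10}; proceeding")
  list(n_major = 4L, n_rare = as.integer(n_rare),
       major_fraction = major_fraction, rare_pattern = rare_pattern)
}

#' Lay out cells and spatial domains on layered tissue sections
#'
#' Cells are placed uniformly in a rectangle; four vertical bands of equal
#' baseline width define the domains. On sections beyond the first, each
#' interior boundary is shifted independently by
#' `Uniform(-shift, +shift)` with `shift = shift_fraction * width`; shifts
#' that would make bands cross are clamped (with a warning).
#'
#' @param n_cells Cells per section.
#' @param L Number of sections.
#' @param shift_fraction Boundary shift as a fraction of tissue width.
#' @param width,height Tissue rectangle.
#' @return List with one element per section: `coords` (n x 2) and `z`
#'   (domain label per cell), plus the `boundaries` used.
#' @export
layout_domains <- function(n_cells, L = 1, shift_fraction = 0.10,
                           width = 5000, height = 1000) {
  stopifnot(L >= 1, n_cells >= 4)
  base <- width * c(1, 2, 3) / 4
  shift <- shift_fraction * width
  lapply(seq_len(L), function(l) {
    b <- base
    if (l > 1L) {
      b <- base + stats::runif(3L, -shift, shift)
      if (is.unsorted(b, strictly = TRUE) || b[1] <= 0 || b[3] >= width) {
        warning("boundary shift caused band inversion; clamping")
        b <- pmin(pmax(sort(b), width * 0.02), width * 0.98)
        b <- cummax(b + c(0, 1e-9, 2e-9))
      }
    }
    coords <- cbind(x = stats::runif(n_cells, 0, width),
                    y = stats::runif(n_cells, 0, height))
    z <- as.integer(findInterval(coords[, 1L], b) + 1L)
    list(coords = coords, z = z, boundaries = b)
  })
}

# C x R composition matrix of one scenario (4 types, 4 domains); the missing
# type of domain r is the "next" type, so each domain misses a different one
scenario_pi <- function(scenario) {
  pi <- matrix(0, 4, 4)
  for (r in 1:4) {
    dominant <- r
    missing <- r %% 4 + 1
    others <- setdiff(1:4, c(dominant, missing))
    pi[, r] <- switch(scenario,
      I = { v <- numeric(4); v[dominant] <- 1; v },
      II = { v <- numeric(4); v[dominant] <- 0.90; v[others] <- 0.05; v },
      III = { v <- numeric(4); v[dominant] <- 0.50; v[others] <- 0.25; v },
      IV = { v <- numeric(4); v[c(dominant, others)] <- 1 / 3; v },
      stop("unknown scenario: ", scenario))
  }
  pi
}

#' Assign cell types from a scenario composition
#'
#' Draws each cell's type from the categorical composition of its domain.
#'
#' @param true_z Integer domain labels (values in 1..4).
#' @param scenario Scenario code `"I"`-`"IV"`.
#' @return List with `c` (types) and `pi` (the 4 x 4 composition matrix).
#' @export
assign_types <- function(true_z, scenario) {
  pi <- scenario_pi(scenario)
  c <- vapply(true_z, function(r) {
    sample.int(4L, 1L, prob = pi[, r])
  }, integer(1))
  list(c = c, pi = pi)
}

#' Assign cell types with rare types present
#'
#' Major types follow the 2:1:1 within-domain composition on
#' `major_fraction` of the cells; rare types share the remainder equally,
#' uniformly over the tissue or confined to single domains (round-robin over
#' the four domains). Compositions are constructed so each rare type holds
#' the same overall fraction of cells under both patterns.
#'
#' @param true_z Integer domain labels (1..4).
#' @param config List from [rare_config()].
#' @return List with `c`, `pi` (C x 4 with C = 4 + n_rare) and
#'   `rare_type_ids`.
#' @export
assign_types_rare <- function(true_z, config) {
  n_rare <- config$n_rare
  fmaj <- config$major_fraction
  C <- 4L + n_rare
  pi <- matrix(0, C, 4)
  rare_share <- (1 - fmaj) / n_rare          # overall fraction per rare type
  rare_domain <- ((seq_len(n_rare) - 1L) %% 4L) + 1L
  for (r in 1:4) {
    if (config$rare_pattern == "random") {
      pi[4L + seq_len(n_rare), r] <- rare_share
    } else {
      # a resident rare type takes 4 * rare_share of this domain's cells so
      # that, with equal-sized domains, it still holds rare_share of all cells
      mine <- which(rare_domain == r)
      pi[4L + mine, r] <- 4 * rare_share
    }
    rare_tot <- sum(pi[4L + seq_len(n_rare), r])
    dominant <- r
    missing <- r %% 4 + 1
    others <- setdiff(1:4, c(dominant, missing))
    maj <- 1 - rare_tot
    pi[dominant, r] <- maj * 0.5
    pi[others, r] <- maj * 0.25
  }
  c <- vapply(true_z, function(r) {
    sample.int(C, 1L, prob = pi[, r])
  }, integer(1))
  list(c = c, pi = pi, rare_type_ids = 4L + seq_len(n_rare))
}

#' Simulate expression counts (splat-style)
#'
#' Per-gene base means are gamma distributed; each (gene, type) pair is
#' differentially expressed with probability `de_prob`, with a log-normal
#' multiplicative factor (`meanlog = de_facloc`, `sdlog = de_facscale`) that
#' is inverted for the half of DE genes chosen as downregulated. Expected
#' per-cell expression is the type's mean profile renormalized to a
#' log-normal library size; a BCV-style gamma mixture adds mean-variance
#' overdispersion before Poisson sampling.
#'
#' @param true_c Integer cell-type labels.
#' @param config `spadom_sim_config` (uses the expression parameters).
#' @return List with `counts` (genes x cells integer matrix),
#'   `de_gene_flags` (genes x types character matrix: `"up"`, `"down"`,
#'   `"none"`), `base_means`, `lib_sizes`.
#' @export
simulate_counts_splat <- function(true_c, config) {
  G <- config$n_genes
  C <- max(true_c)
  N <- length(true_c)
  base <- stats::rgamma(G, shape = config$mean_shape, rate = config$mean_rate)
  flags <- matrix("none", G, C)
  fac <- matrix(1, G, C)
  if (config$de_prob > 0) {
    for (k in seq_len(C)) {
      is_de <- stats::runif(G) < config$de_prob
      f <- stats::rlnorm(G, meanlog = config$de_facloc,
                         sdlog = config$de_facscale)
      up <- stats::runif(G) < 0.5
      fac[is_de & up, k] <- f[is_de & up]
      fac[is_de & !up, k] <- 1 / f[is_de & !up]
      flags[is_de & up, k] <- "up"
      flags[is_de & !up, k] <- "down"
    }
  }
  type_mean <- base * fac                     # G x C
  type_prop <- sweep(type_mean, 2L, colSums(type_mean), "/")
  lib <- stats::rlnorm(N, meanlog = config$lib_loc, sdlog = config$lib_scale)
  mu <- sweep(type_prop[, true_c, drop = FALSE], 2L, lib, "*")  # G x N
  # per-gene BCV inflation, then gamma-Poisson
  chi <- stats::rchisq(G, df = config$bcv_df)
  infl <- sqrt(config$bcv_df / chi)
  bcv <- (config$bcv_common + 1 / sqrt(pmax(mu, 1e-12))) * infl
  shape <- 1 / bcv^2
  lambda <- matrix(stats::rgamma(G * N, shape = shape, scale = mu / shape),
                   G, N)
  counts <- matrix(stats::rpois(G * N, lambda), G, N)
  storage.mode(counts) <- "integer"
  list(counts = counts, de_gene_flags = flags, de_factors = fac,
       base_means = base, lib_sizes = lib)
}

#' Randomly exclude genes
#'
#' Keeps a uniformly random subset of `n_retained` genes; reproducible under
#' the session seed.
#'
#' @param counts Genes x cells matrix.
#' @param n_retained Number of genes to keep.
#' @return The row-subset matrix, plus attribute `retained` (row indices).
#' @export
exclude_genes <- function(counts, n_retained) {
  G <- nrow(counts)
  if (n_retained <= 0) stop("n_retained must be positive")
  if (n_retained > G) stop("n_retained exceeds the number of genes")
  keep <- sort(sample.int(G, n_retained))
  out <- counts[keep, , drop = FALSE]
  attr(out, "retained") <- keep
  out
}

#' Simulate a full spatial transcriptomic experiment
#'
#' End-to-end generator: layered tissue layout, scenario (or rare-type)
#' cell-type assignment, splat-style counts, optional random gene exclusion.
#' All randomness flows from `config$seed`.
#'
#' @param config A `spadom_sim_config`.
#' @return A `spadom_sim` list: `counts` (genes x cells), `gene_ids`,
#'   `cell_ids`, `section_of_cell`, `coords` (cells x 2), `true_c`, `true_z`,
#'   `true_pi`, `de_gene_flags`, `rare_type_ids` (if any), `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "spadom_sim_config"))
  set.seed(config$seed)
  L <- config$n_sections
  lay <- layout_domains(config$n_cells_per_section, L,
                        config$boundary_shift_fraction, config$width,
                        config$height)
  coords <- do.call(rbind, lapply(lay, `[[`, "coords"))
  true_z <- unlist(lapply(lay, `[[`, "z"))
  section <- rep(seq_len(L), each = config$n_cells_per_section)
  if (is.null(config$rare_config)) {
    asg <- assign_types(true_z, config$scenario)
    rare_ids <- integer(0)
  } else {
    asg <- assign_types_rare(true_z, config$rare_config)
    rare_ids <- asg$rare_type_ids
  }
  cnt <- simulate_counts_splat(asg$c, config)
  counts <- cnt$counts
  flags <- cnt$de_gene_flags
  gene_ids <- sprintf("gene%04d", seq_len(nrow(counts)))
  if (!is.null(config$genes_retained)) {
    counts <- exclude_genes(counts, config$genes_retained)
    keep <- attr(counts, "retained")
    gene_ids <- gene_ids[keep]
    flags <- flags[keep, , drop = FALSE]
  }
  cell_ids <- sprintf("cell%05d", seq_len(ncol(counts)))
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_ids
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 section_of_cell = section, coords = coords,
                 true_c = asg$c, true_z = true_z, true_pi = asg$pi,
                 de_gene_flags = flags, rare_type_ids = rare_ids,
                 config = config),
            class = "spadom_sim")
}

#' @export
#' @method print spadom_sim
print.spadom_sim <- function(x, ...) {
  cat(sprintf(paste0("synthetic spatial experiment: %d genes x %d cells, ",
                     "%d section(s), scenario %s, %d cell types, ",
                     "%d domains\n"),
              nrow(x$counts), ncol(x$counts), x$config$n_sections,
              x$config$scenario, nrow(x$true_pi), ncol(x$true_pi)))
  invisible(x)
}
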