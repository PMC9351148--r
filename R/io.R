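#' Read expression and coordinates for one or more sections
#'
#' The manifest is a CSV with columns `section_id`, `expr_path`,
#' `coords_path` (paths relative to the manifest's directory). Expression
#' files are either Matrix Market (`.mtx`, with `<stem>.genes.tsv` and
#' `<stem>.barcodes.tsv` sidecars, or `genes.tsv`/`barcodes.tsv` next to the
#' matrix) or dense CSV with gene ids in the first column and cell ids as the
#' header. Coordinates are CSV with columns `cell_id`, `x`, `y`. Cells are
#' intersected with their coordinates by `cell_id` (cells without
#' coordinates are dropped, with a message); genes are intersected across
#' sections to a common set.
#'
#' @param manifest Path to the manifest CSV.
#' @return List with `counts` (common genes x all cells, ordered by section),
#'   `gene_ids`, `cell_ids`, `section_of_cell`, `coords` (cells x 2),
#'   `sections` (section ids in order).
#' @export
read_spatial_inputs <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("section_id", "expr_path", "coords_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns section_id, expr_path, coords_path")
  base <- dirname(normalizePath(manifest))
  secs <- lapply(seq_len(nrow(man)), function(i) {
    expr <- read_expr(file.path(base, man$expr_path[i]))
    coo <- utils::read.csv(file.path(base, man$coords_path[i]),
                           stringsAsFactors = FALSE)
    if (!all(c("cell_id", "x", "y") %in% names(coo)))
      stop("coordinates file must have columns cell_id, x, y")
    common <- intersect(colnames(expr), coo$cell_id)
    dropped <- ncol(expr) - length(common)
    if (dropped > 0)
      message(sprintf("section %s: dropped %d cell(s) without coordinates",
                      man$section_id[i], dropped))
    if (length(common) == 0)
      stop("no cells shared between expression and coordinates")
    coo <- coo[match(common, coo$cell_id), ]
    list(expr = expr[, common, drop = FALSE],
         coords = cbind(x = coo$x, y = coo$y),
         cell_ids = common, section_id = man$section_id[i])
  })
  genes <- Reduce(intersect, lapply(secs, function(s) rownames(s$expr)))
  if (length(genes) == 0) stop("no genes common to all sections")
  counts <- do.call(cbind, lapply(secs, function(s)
    as.matrix(s$expr[genes, , drop = FALSE])))
  storage.mode(counts) <- "integer"
  list(counts = counts, gene_ids = genes,
       cell_ids = unlist(lapply(secs, `[[`, "cell_ids")),
       section_of_cell = rep(seq_along(secs),
                             vapply(secs, function(s) length(s$cell_ids),
                                    integer(1))),
       coords = do.call(rbind, lapply(secs, `[[`, "coords")),
       sections = man$section_id)
}

read_expr <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    gfile <- if (file.exists(paste0(stem, ".genes.tsv")))
      paste0(stem, ".genes.tsv") else file.path(dirname(path), "genes.tsv")
    bfile <- if (file.exists(paste0(stem, ".barcodes.tsv")))
      paste0(stem, ".barcodes.tsv")
    else file.path(dirname(path), "barcodes.tsv")
    rownames(m) <- utils::read.table(gfile)[, 1L]
    colnames(m) <- utils::read.table(bfile)[, 1L]
    m
  } else {
    d <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    as.matrix(d)
  }
}

#' Write a simulated experiment to disk
#'
#' Emits, per section, expression (`CSV` or `MTX` + sidecars) and a
#' coordinates CSV, plus a `manifest.csv` and truth files (`true_labels.csv`,
#' `true_pi.csv`, `de_gene_flags.csv`) — the same formats
#' [read_spatial_inputs()] consumes.
#'
#' @param sim A `spadom_sim` object.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"mtx"` for the expression matrices.
#' @return The manifest path, invisibly.
#' @export
write_sim <- function(sim, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- sim$config$n_sections
  rows <- lapply(seq_len(L), function(l) {
    idx <- which(sim$section_of_cell == l)
    cnt <- sim$counts[, idx, drop = FALSE]
    if (format == "csv") {
      expr_path <- sprintf("section%d_expr.csv", l)
      utils::write.csv(as.data.frame(cnt), file.path(dir, expr_path))
    } else {
      expr_path <- sprintf("section%d_expr.mtx", l)
      Matrix::writeMM(Matrix::Matrix(cnt, sparse = TRUE),
                      file.path(dir, expr_path))
      stem <- file.path(dir, sub("\\.mtx$", "", expr_path))
      utils::write.table(rownames(cnt), paste0(stem, ".genes.tsv"),
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
      utils::write.table(colnames(cnt), paste0(stem, ".barcodes.tsv"),
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
    coords_path <- sprintf("section%d_coords.csv", l)
    utils::write.csv(data.frame(cell_id = sim$cell_ids[idx],
                                x = sim$coords[idx, 1L],
                                y = sim$coords[idx, 2L]),
                     file.path(dir, coords_path), row.names = FALSE)
    data.frame(section_id = l, expr_path = expr_path,
               coords_path = coords_path)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  utils::write.csv(data.frame(cell_id = sim$cell_ids,
                              section_id = sim$section_of_cell,
                              cell_type = sim$true_c, domain = sim$true_z),
                   file.path(dir, "true_labels.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$true_pi),
                   file.path(dir, "true_pi.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$de_gene_flags),
                   file.path(dir, "de_gene_flags.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Export a neighbour graph's edge list
#'
#' Writes the undirected edge set as a two-column CSV (`i`, `j`) of 0-based
#' node indices.
#'
#' @param graph A `spadom_graph`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  utils::write.csv(data.frame(i = graph$edges[, 1L] - 1L,
                              j = graph$edges[, 2L] - 1L),
                   path, row.names = FALSE)
  invisible(path)
}

#' Checkpoint and restore a model state
#'
#' `save_state()` serializes one MCMC configuration (labels plus parameter
#' matrices) to plain CSV files in a directory; `load_state()` restores it,
#' e.g. to resume a run via the `init` argument of [run_mcmc()].
#'
#' @param state A `spadom_state` (see [init_state()]).
#' @param dir Checkpoint directory (created if missing).
#' @return `save_state()` the directory, invisibly; `load_state()` the state.
#' @export
save_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(c = state$c, z = state$z),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  for (f in c("mu", "Sigma", "pi")) {
    utils::write.csv(as.data.frame(state[[f]]),
                     file.path(dir, paste0(f, ".csv")), row.names = FALSE)
  }
  utils::write.csv(data.frame(lam = state$lam, beta = state$beta),
                   file.path(dir, "scalars.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_state
#' @export
load_state <- function(dir) {
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  sc <- utils::read.csv(file.path(dir, "scalars.csv"))
  state <- list(c = as.integer(labs$c), z = as.integer(labs$z),
                mu = as.matrix(utils::read.csv(file.path(dir, "mu.csv"))),
                Sigma = as.matrix(utils::read.csv(file.path(dir, "Sigma.csv"))),
                lam = as.numeric(sc$lam),
                pi = as.matrix(utils::read.csv(file.path(dir, "pi.csv"))),
                beta = sc$beta[1L])
  dimnames(state$mu) <- dimnames(state$Sigma) <- dimnames(state$pi) <- NULL
  class(state) <- "spadom_state"
  state
}

#' Run the full analysis pipeline from a configuration
#'
#' Reads a manifest, preprocesses, builds the graphs, fits the model, and
#' writes labels, compositions, traces, a config snapshot and a run log to
#' `out_dir`. Reruns with the same configuration and seed reproduce the
#' outputs exactly.
#'
#' @param config A named list (or path to a YAML file) with fields
#'   `manifest`, `out_dir`, `C`, `R` and optionally `J` (20), `k` (6),
#'   `n_iter` (10000), `burn_in` (`n_iter/2`), `seed` (1), `beta_max` (4),
#'   `alignment` (`"standardize"` for multi-section input, else `"none"`).
#' @return The `spadom_fit`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("manifest", "out_dir", "C", "R"))
    if (is.null(config[[f]])) stop("config field missing: ", f)
  cfg <- utils::modifyList(list(J = 20, k = 6, n_iter = 10000,
                                burn_in = NULL, seed = 1, beta_max = 4,
                                alignment = NULL), config)
  if (is.null(cfg$burn_in)) cfg$burn_in <- cfg$n_iter / 2
  inp <- read_spatial_inputs(cfg$manifest)
  fit <- spadom(inp$counts, inp$coords, section = inp$section_of_cell,
                C = cfg$C, R = cfg$R, J = cfg$J, k = cfg$k,
                n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                beta_max = cfg$beta_max, alignment = cfg$alignment,
                seed = cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(cell_id = inp$cell_ids,
                              section_id = inp$section_of_cell,
                              cell_type = fit$c, domain = fit$z),
                   file.path(cfg$out_dir, "labels.csv"), row.names = FALSE)
  pi <- as.data.frame(fit$pi)
  names(pi) <- sprintf("domain%d", seq_len(ncol(pi)))
  utils::write.csv(pi, file.path(cfg$out_dir, "pi.csv"), row.names = FALSE)
  feat <- as.data.frame(unclass_features(fit$features))
  names(feat) <- sprintf("PC%d", seq_len(ncol(feat)))
  utils::write.csv(cbind(data.frame(cell_id = inp$cell_ids,
                                    section_id = inp$section_of_cell), feat),
                   file.path(cfg$out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(data.frame(draw = seq_along(fit$samples$beta_draws),
                              beta = fit$samples$beta_draws,
                              log_post = fit$samples$log_post_draws),
                   file.path(cfg$out_dir, "trace.csv"), row.names = FALSE)
  snapshot <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg, snapshot)
  log_lines <- c(sprintf("seed: %s", cfg$seed),
                 sprintf("config_md5: %s",
                         unname(tools::md5sum(snapshot))),
                 sprintf("beta_accept_rate: %.4f",
                         fit$samples$beta_accept_rate),
                 sprintf("beta_hat: %.4f", fit$beta))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(fit)
}
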