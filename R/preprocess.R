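#' Library-size normalization and log2 transformation
#'
#' Scales each cell's counts to a common total (`target_sum`), then applies
#' `log2(x + 1)` elementwise. Cells with zero total counts pass through as
#' all-zero columns.
#'
#' @param counts Non-negative count matrix, genes in rows, cells in columns.
#' @param target_sum Positive scalar; the post-scaling total count per cell.
#'   Defaults to the median library size across cells, a scale-free choice
#'   that does not depend on sequencing depth or platform.
#' @return A numeric matrix of the same dimensions (and dimnames) on the
#'   log2 scale.
#' @examples
#' m <- matrix(c(1, 3, 0, 0), nrow = 2)
#' normalize_log_counts(m, target_sum = 4)
#' @export
normalize_log_counts <- function(counts, target_sum = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (is.null(target_sum)) {
    target_sum <- stats::median(lib[lib > 0])
    if (!is.finite(target_sum)) stop("all cells have zero counts")
  }
  if (target_sum <= 0) stop("target_sum must be positive")
  scale <- ifelse(lib > 0, target_sum / lib, 0)
  log2(sweep(counts, 2L, scale, "*") + 1)
}

#' Extract principal-component expression features
#'
#' Projects cells onto the top `J` principal axes of the gene-centered,
#' log-normalized expression matrix. Genes are centered but not unit-scaled:
#' the inputs are already on a common log scale. Component signs follow a
#' deterministic convention (the largest-magnitude loading of each component
#' is positive) so repeated runs give identical features.
#'
#' @param x Normalized expression matrix, genes in rows, cells in columns.
#' @param J Number of components to keep (default 20).
#' @param section_of_cell Optional integer vector (one entry per cell) of
#'   section memberships, attached to the result.
#' @return A `spadom_features` object: a cells x J matrix with attribute
#'   `section_of_cell`.
#' @export
extract_pcs <- function(x, J = 20, section_of_cell = NULL) {
  x <- as.matrix(x)
  if (J < 1) stop("J must be a positive integer")
  if (J > min(dim(x))) stop("J must not exceed min(genes, cells)")
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  r <- sum(p$sdev > max(p$sdev) * 1e-10)
  if (J > r) {
    warning(sprintf("requested J = %d exceeds rank %d; reduced to rank", J, r))
    J <- r
  }
  rot <- p$rotation[, seq_len(J), drop = FALSE]
  feat <- p$x[, seq_len(J), drop = FALSE]
  for (j in seq_len(J)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      feat[, j] <- -feat[, j]
    }
  }
  if (is.null(section_of_cell)) section_of_cell <- rep(1L, nrow(feat))
  as_features(feat, section_of_cell)
}

as_features <- function(m, section_of_cell) {
  m <- as.matrix(m)
  stopifnot(length(section_of_cell) == nrow(m), all(is.finite(m)))
  attr(m, "section_of_cell") <- as.integer(section_of_cell)
  class(m) <- c("spadom_features", class(m))
  m
}

#' @export
#' @method print spadom_features
print.spadom_features <- function(x, ...) {
  sec <- attr(x, "section_of_cell")
  cat(sprintf("expression features: %d cells x %d components, %d section(s)\n",
              nrow(x), ncol(x), length(unique(sec))))
  invisible(x)
}

#' Align expression features across tissue sections
#'
#' Multi-section fits assume the expression features of the sections live on
#' a common scale. `method = "standardize"` centers and unit-scales each
#' feature within each section; `"none"` is the identity (appropriate for a
#' single section); `"external"` applies a user-supplied alignment routine
#' (e.g. a Harmony wrapper) which must return a matrix of the same shape.
#'
#' @param features A `spadom_features` matrix (see [extract_pcs()]).
#' @param method One of `"none"`, `"standardize"`, `"external"`.
#' @param fun Alignment function for `method = "external"`; called as
#'   `fun(features, section_of_cell)`.
#' @return Aligned `spadom_features` of the same shape.
#' @export
align_sections <- function(features,
                           method = c("none", "standardize", "external"),
                           fun = NULL) {
  method <- match.arg(method)
  sec <- attr(features, "section_of_cell")
  if (is.null(sec)) sec <- rep(1L, nrow(features))
  if (method == "none") return(features)
  if (method == "external") {
    if (!is.function(fun)) stop("method = 'external' requires `fun`")
    out <- fun(unclass_features(features), sec)
    if (!identical(dim(out), dim(unclass_features(features))))
      stop("external alignment must preserve the feature matrix shape")
    return(as_features(out, sec))
  }
  m <- unclass_features(features)
  for (l in unique(sec)) {
    idx <- which(sec == l)
    if (length(idx) < 2L)
      stop(sprintf("section %s has fewer than 2 cells; cannot standardize", l))
    sub <- scale(m[idx, , drop = FALSE])
    sub[!is.finite(sub)] <- 0  # constant feature within a section
    m[idx, ] <- sub
  }
  as_features(m, sec)
}

unclass_features <- function(x) {
  attr(x, "section_of_cell") <- NULL
  class(x) <- NULL
  x
}
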