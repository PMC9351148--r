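#' Build the spatial k-nearest-neighbour graph of one tissue section
#'
#' Each cell is connected to its `k` nearest neighbours under Euclidean
#' distance; the directed kNN relation is symmetrized by union into an
#' undirected edge set. Distance ties are broken in favour of the smaller
#' cell index, so the graph is deterministic even with duplicated
#' coordinates.
#'
#' @param coords Numeric matrix of cell coordinates, cells x 2.
#' @param k Number of nearest neighbours (default 6, roughly the contact
#'   number of a cell in a 2-D monolayer).
#' @param section_id Optional identifier stored on the graph.
#' @return A `spadom_graph`: list with `n_nodes`, `edges` (two-column integer
#'   matrix of unordered pairs, i < j, 1-based) and `section_id`.
#' @export
knn_graph <- function(coords, k = 6, section_id = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of cells")
  d <- as.matrix(stats::dist(coords))
  edges <- matrix(0L, nrow = n * k, ncol = 2L)
  pos <- 0L
  for (i in seq_len(n)) {
    # order by distance, ties by smaller index; drop self
    o <- order(d[i, ], seq_len(n))
    o <- o[o != i][seq_len(k)]
    for (j in o) {
      pos <- pos + 1L
      edges[pos, ] <- c(min(i, j), max(i, j))
    }
  }
  edges <- unique(edges[seq_len(pos), , drop = FALSE])
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(list(n_nodes = n, edges = edges, section_id = section_id),
            class = "spadom_graph")
}

#' @export
#' @method print spadom_graph
print.spadom_graph <- function(x, ...) {
  cat(sprintf("spatial kNN graph: %d nodes, %d undirected edges (section %s)\n",
              x$n_nodes, nrow(x$edges), x$section_id))
  invisible(x)
}

validate_graph <- function(g) {
  stopifnot(inherits(g, "spadom_graph"),
            all(g$edges >= 1L), all(g$edges <= g$n_nodes),
            all(g$edges[, 1L] < g$edges[, 2L]),
            !anyDuplicated(g$edges))
  invisible(g)
}

# regular grid lattice with 4-neighbour edges; used for sampler diagnostics
lattice_graph <- function(nr, nc) {
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
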