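#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, from the contingency
#' table of pair counts: 1 for identical partitions (up to label
#' permutation), about 0 for independent ones.
#'
#' @param pred,truth Label vectors of equal length (any atomic type).
#' @return Scalar ARI.
#' @export
ari <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  tab <- table(pred, truth)
  n <- length(pred)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sij - expected) / (maxi - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the arithmetic
#' mean of their entropies; lies in `[0, 1]`. Degenerate single-class inputs
#' return 0 with a warning.
#'
#' @param pred,truth Label vectors of equal length.
#' @return Scalar NMI.
#' @export
nmi <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  n <- length(pred)
  tab <- table(pred, truth) / n
  pi <- rowSums(tab)
  pj <- colSums(tab)
  hi <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (hi == 0 && hj == 0) {
    warning("both labelings are single-class; NMI undefined, returning 0")
    return(0)
  }
  mi <- 0
  for (a in seq_along(pi)) {
    for (b in seq_along(pj)) {
      if (tab[a, b] > 0)
        mi <- mi + tab[a, b] * log(tab[a, b] / (pi[a] * pj[b]))
    }
  }
  unname(mi / ((hi + hj) / 2))
}

#' Match predicted labels to a reference labeling
#'
#' Finds the permutation of the predicted labels that maximizes total
#' contingency-table agreement with the reference (optimal assignment;
#' rectangular cases are padded with zeros, so surplus predicted classes
#' keep fresh labels). Label spaces may differ in size.
#'
#' @param pred,truth Integer label vectors of equal length.
#' @return The relabeled `pred`, with attribute `perm` giving the new label
#'   of each original predicted label.
#' @export
match_labels <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  kp <- max(pred)
  kt <- max(truth)
  m <- max(kp, kt)
  tab <- matrix(0, kp, m)
  tt <- table(factor(pred, levels = seq_len(kp)),
              factor(truth, levels = seq_len(kt)))
  tab[, seq_len(kt)] <- tt
  perm <- solve_assignment(max(tab) - tab)
  out <- perm[pred]
  attr(out, "perm") <- perm
  out
}

#' Per-rare-type F1 and Matthews correlation
#'
#' Matches the predicted labels to the truth, then scores each rare type as
#' a one-vs-rest binary problem; the summary is the unweighted mean over
#' rare types. A rare type never predicted scores F1 = 0 (and MCC = 0).
#'
#' @param pred,truth Integer label vectors.
#' @param rare_type_ids True label values of the rare types.
#' @return List with `per_type` (data.frame: type, F1, MCC) and the means
#'   `F1`, `MCC`.
#' @export
rare_type_scores <- function(pred, truth, rare_type_ids) {
  matched <- match_labels(pred, truth)
  per <- t(vapply(rare_type_ids, function(t) {
    p <- matched == t
    a <- truth == t
    tp <- sum(p & a); fp <- sum(p & !a); fn <- sum(!p & a); tn <- sum(!p & !a)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    c(F1 = f1, MCC = mcc)
  }, numeric(2)))
  list(per_type = data.frame(type = rare_type_ids, F1 = per[, "F1"],
                             MCC = per[, "MCC"]),
       F1 = mean(per[, "F1"]), MCC = mean(per[, "MCC"]))
}

#' RMSE between estimated and true composition matrices
#'
#' Applies the cell-type and domain label permutations (from
#' [match_labels()]) to the rows and columns of the estimate, then computes
#' the element-wise root-mean-square error over the C x R matrix.
#'
#' @param pi_hat,pi_true C x R composition matrices.
#' @param perm_c,perm_z Optional permutations (`perm` attribute of
#'   [match_labels()]); identity if `NULL`.
#' @return Scalar RMSE.
#' @export
composition_rmse <- function(pi_hat, pi_true, perm_c = NULL, perm_z = NULL) {
  if (!all(dim(pi_hat) == dim(pi_true))) stop("composition shapes differ")
  aligned <- pi_hat
  if (!is.null(perm_c)) aligned[perm_c, ] <- aligned
  if (!is.null(perm_z)) aligned[, perm_z] <- aligned
  sqrt(mean((aligned - pi_true)^2))
}
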