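# Linear assignment (Hungarian / shortest augmenting path, O(n^3)).
# Used for label matching between partitions and for ECR relabeling.

# cost: n x m numeric matrix with n <= m. Returns an integer vector `a` of
# length n with distinct entries in 1..m minimizing sum(cost[i, a[i]]).
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n > m) stop("solve_assignment requires nrow <= ncol")
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j + 1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) a[p[j + 1]] <- j
  a
}

# permutation of draw labels (1..K) maximizing agreement with a pivot
# allocation; ties broken deterministically by the assignment order
best_label_permutation <- function(draw, pivot, K) {
  tab <- table(factor(draw, levels = seq_len(K)),
               factor(pivot, levels = seq_len(K)))
  solve_assignment(max(tab) - unclass(tab))
}
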