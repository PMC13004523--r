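# Hungarian (Kuhn-Munkres) assignment via shortest augmenting paths with
# dual potentials, O(n^3). Written here because no installed package exposes
# linear assignment; verified against exhaustive permutation in the tests.

#' Minimum-cost assignment
#'
#' Solves the linear assignment problem for a rectangular cost matrix
#' (rows <= columns after internal padding): finds the column for each row
#' minimizing the total cost.
#'
#' @param cost Numeric cost matrix.
#' @return Integer vector: assigned column per row (0 for rows matched to a
#'   padding column, only possible when rows > columns).
#' @export
solve_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  C <- matrix(0, n, n)
  C[seq_len(nr), seq_len(nc)] <- cost
  # potentials u (rows), v (cols); p[j] = row assigned to column j (0 = none)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- C[i0, j] - u[i0 + 1] - v[j + 1]
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
      for (j in 0:n) {
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
  assign_col <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1] > 0) assign_col[p[j + 1]] <- j
  }
  out <- assign_col[seq_len(nr)]
  out[out > nc] <- 0L
  out
}
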