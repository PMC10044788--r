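# Globally optimal one-to-one assignment (Hungarian algorithm with
# potentials, O(n^2 m)). No linear-assignment solver is available among the
# package's dependencies, so the solver is implemented here and property-
# tested against the exhaustive-permutation oracle.

#' Minimum-cost one-to-one assignment
#'
#' Solves \code{min sum_i cost[i, assign(i)]} over injective assignments of
#' rows to columns (requires \code{nrow <= ncol}). Deterministic: equal-cost
#' optima resolve to the same assignment for the same input matrix.
#'
#' @param cost numeric cost matrix, rows <= columns.
#' @return integer vector: for each row, the assigned column.
#' @examples
#' solveAssignment(matrix(c(1, 2, 3, 0.5), 2, 2))  # rows -> cols 1, 2
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0) return(integer())
  if (n > m) stop("cost matrix must have nrow <= ncol")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  J0 <- m + 1L                       # virtual start column
  u <- rep(0, n)
  v <- rep(0, J0)
  p <- rep(0L, J0)                   # p[j]: row currently assigned to col j
  way <- rep(0L, m)
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, m)
    used <- rep(FALSE, J0)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(J0)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= m) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) ans[p[j]] <- j
  ans
}
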