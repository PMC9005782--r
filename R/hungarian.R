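#' Solve the linear assignment problem (Kuhn-Munkres / Hungarian algorithm)
#'
#' Finds the permutation of columns minimising the total cost of a square
#' cost matrix, in O(n^3) using the potentials + shortest augmenting path
#' formulation. Used to resolve ambiguous atom correspondences within
#' exchangeability classes of functional atoms (e.g. the two carboxylate
#' oxygens of Asp/Glu, or the His ring atoms), where the cost is the pairwise
#' Euclidean distance after a crude rigid fit.
#'
#' @param cost numeric square matrix; `cost[i, j]` is the cost of assigning
#'   row `i` to column `j`.
#' @return integer vector `a` with `a[i]` the column assigned to row `i`;
#'   attribute `"cost"` holds the total assignment cost.
#' @examples
#' m <- matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, 3, byrow = TRUE)
#' solve_assignment(m)
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost)) {
    stop("solve_assignment() needs a square cost matrix", call. = FALSE)
  }
  if (any(!is.finite(cost))) {
    stop("solve_assignment() needs finite costs", call. = FALSE)
  }
  n <- nrow(cost)
  if (n == 0L) return(structure(integer(0), cost = 0))
  virt <- n + 1L # virtual column used to seed each augmenting path
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row currently matched to column j (0 = free)
  way <- integer(n + 1L) # predecessor column on the alternating path
  for (i in seq_len(n)) {
    p[virt] <- i
    j0 <- virt
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
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
      if (j0 == virt) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  total <- sum(cost[cbind(seq_len(n), assignment)])
  structure(assignment, cost = total)
}
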