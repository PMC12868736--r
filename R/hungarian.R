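# Minimum-cost one-to-one assignment (Hungarian / Jonker-Volgenant).
#
# Shortest-augmenting-path formulation with dual potentials, O(n^3).
# Rectangular instances are padded to square with zero-cost dummy rows or
# columns; every dummy pairing costs the same, so the real rows' assignment
# is unchanged by the padding.

#' Solve the minimum-cost assignment problem
#'
#' Finds the one-to-one assignment of rows to columns of a cost matrix that
#' minimizes the total cost, using the Hungarian algorithm in its
#' shortest-augmenting-path (Jonker-Volgenant) form. For rectangular
#' matrices, `min(nrow, ncol)` pairs are returned.
#'
#' @param cost Numeric matrix of non-negative finite costs.
#' @return A data.frame with columns `row`, `col`, `cost`, sorted by `row`;
#'   one row per assigned pair. The attribute `"total_cost"` carries the
#'   optimal total.
#' @export
#' @examples
#' solve_assignment_lsap(matrix(c(0.1, 0.3, 0.4, 0.2), 2, 2))
solve_assignment_lsap <- function(cost) {
  assert_that(is.matrix(cost) && is.numeric(cost),
              "cost must be a numeric matrix")
  assert_that(all(is.finite(cost)), "cost entries must be finite")
  nr <- nrow(cost); nc <- ncol(cost)
  assert_that(nr >= 1L && nc >= 1L, "cost matrix must be non-empty")
  n <- max(nr, nc)
  a <- matrix(0, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost

  # p[j] = row currently assigned to column j (0 = free); column 0 is a
  # virtual column used to seed each augmenting search.
  INF <- Inf
  u <- numeric(n + 1L)   # row potentials, index shifted by 1 (u[1] unused)
  v <- numeric(n + 1L)   # column potentials, v[1] is virtual column 0
  p <- integer(n + 1L)   # p[1] is virtual column 0
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- a[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedcols <- which(used) - 1L          # includes virtual column 0
      rows_in_tree <- p[usedcols + 1L]
      u[rows_in_tree + 1L] <- u[rows_in_tree + 1L] + delta
      v[usedcols + 1L] <- v[usedcols + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  col_of <- integer(n)
  col_of[p[-1L]] <- seq_len(n)
  rows <- seq_len(nr)
  cols <- col_of[rows]
  keep <- cols <= nc
  out <- data.frame(row = rows[keep], col = cols[keep],
                    cost = cost[cbind(rows[keep], cols[keep])])
  out <- out[order(out$row), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_cost") <- sum(out$cost)
  out
}
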