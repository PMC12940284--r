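#' Cosine similarity between rows of two non-negative matrices
#'
#' @param A,B Matrices with the same number of columns. `B` defaults to `A`.
#' @return `nrow(A)` x `nrow(B)` matrix of cosine similarities.
#' @keywords internal
cosine_rows <- function(A, B = A) {
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop("zero vector supplied to cosine similarity")
  (A %*% t(B)) / outer(na, nb)
}

# Minimum-cost assignment (Hungarian / shortest augmenting path).
# cost: n x m matrix with n <= m. Returns an integer vector of length n:
# the column assigned to each row.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n > m) stop("hungarian_assign requires nrow <= ncol")
  # 1-based translation of the classical potentials algorithm; index 1 in
  # p/v/way is a virtual column.
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j]: row matched to column j-1 (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(m + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
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
      for (j in 1:(m + 1)) {
        if (used[j]) {
          u[p[j] + 1] <- u[p[j] + 1] + delta
          v[j] <- v[j] - delta
        } else {
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
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(m + 1)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Match signature sets by maximal-cosine assignment
#'
#' Finds the one-to-one assignment between rows of `A` (reference) and rows
#' of `B` maximizing total cosine similarity (optimal assignment, not greedy).
#' When the sets differ in size, `min(nrow(A), nrow(B))` pairs are returned.
#'
#' @param A,B Non-negative matrices with identical column count.
#' @return Data frame with columns `a`, `b` (row indices) and `cosine`,
#'   ordered by `a`.
#' @export
match_signatures <- function(A, B) {
  sim <- cosine_rows(A, B)
  if (nrow(A) <= nrow(B)) {
    j <- hungarian_assign(1 - sim)
    out <- data.frame(a = seq_len(nrow(A)), b = j,
                      cosine = sim[cbind(seq_len(nrow(A)), j)])
  } else {
    i <- hungarian_assign(1 - t(sim))
    out <- data.frame(a = i, b = seq_len(nrow(B)),
                      cosine = sim[cbind(i, seq_len(nrow(B)))])
    out <- out[order(out$a), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
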