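# Minimum-cost perfect matching on a square matrix (Hungarian algorithm,
# potentials + shortest augmenting path, O(n^3)). Returns, for each row, the
# column it is assigned to. Internal; the public surface is solve_assignment().
hungarian <- function(cost) {
  n <- nrow(cost)
  if (is.null(n) || n != ncol(cost)) stop("cost matrix must be square")
  if (n == 0L) return(integer(0))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  u <- numeric(n + 1L)            # row potentials (index i + 1)
  v <- numeric(n + 1L)            # column potentials (index j + 1; j = 0 virtual)
  p <- integer(n + 1L)            # p[j + 1]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])           # unused real columns
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      if (any(upd)) {
        minv[free_j[upd] + 1L] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      k <- which.min(minv[free_j + 1L])
      j1 <- free_j[k]
      delta <- minv[j1 + 1L]
      used_idx <- which(used)
      u[p[used_idx] + 1L] <- u[p[used_idx] + 1L] + delta
      v[used_idx] <- v[used_idx] - delta
      minv[-used_idx] <- minv[-used_idx] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}
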