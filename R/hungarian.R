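# Optimal linear assignment (Hungarian algorithm, O(n^3) shortest augmenting
# path with potentials). Used by the particle tracker to link detections
# between frames by minimizing the total squared displacement.

# cost: n x m matrix (n <= m not required; transposed internally if needed).
# Returns an integer vector a with a[i] = column assigned to row i.
hungarian_assign <- function(cost) {
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost); transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)                    # p[j+1] = row matched to column j
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
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
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  if (transposed) {
    back <- rep(NA_integer_, m)
    for (i in seq_len(n)) back[ans[i]] <- i
    back
  } else {
    ans
  }
}

# Gated matching between two point sets (k x 2 matrices). A pair is linked
# only if its squared distance is below gate^2; unmatched points are allowed
# via dummy nodes at half the gate cost. Returns an integer vector `link`
# with link[i] = index in b matched to a[i], or NA.
gated_match <- function(a, b, gate) {
  na_ <- nrow(a); nb <- nrow(b)
  if (na_ == 0 || nb == 0) return(rep(NA_integer_, na_))
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  BIG <- 1e12
  g2 <- gate^2
  C <- matrix(BIG, na_ + nb, na_ + nb)
  C[seq_len(na_), seq_len(nb)] <- ifelse(d2 <= g2, d2, BIG)
  C[cbind(seq_len(na_), nb + seq_len(na_))] <- g2 / 2   # row i unmatched
  C[cbind(na_ + seq_len(nb), seq_len(nb))] <- g2 / 2    # col j unmatched
  C[na_ + seq_len(nb), nb + seq_len(na_)] <- 0
  sol <- hungarian_assign(C)
  link <- sol[seq_len(na_)]
  link[link > nb] <- NA_integer_
  link
}
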