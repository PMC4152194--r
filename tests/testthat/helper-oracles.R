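# Independent oracles, deliberately implemented along different routes
# than the package code they check.

# Straight double-loop evaluation of the signed modularity index: explicit
# sums over all ordered node pairs of the zero-diagonal weight matrix,
# separately per sign layer.
oracle_modularity <- function(w, p, gamma = 1) {
  p <- as.integer(as_partition(p))
  n <- nrow(w)
  layer <- function(wl) {
    s <- rowSums(wl)
    v <- sum(wl)
    if (v == 0) return(0)
    q <- 0
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (p[i] == p[j])
          q <- q + wl[i, j] - gamma * s[i] * s[j] / v
    q / v
  }
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  qp <- layer(wp); qn <- layer(wn)
  vp <- sum(wp); vn <- sum(wn)
  qp - (vn / (vp + vn)) * qn
}

# Exhaustive maximum of the modularity index over every set partition of
# n nodes, via restricted-growth-string enumeration. Partition scoring
# here uses outer()-based delta matrices, a different route again.
oracle_best_partition <- function(w, gamma = 1) {
  n <- nrow(w)
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  sp <- rowSums(wp); sn <- rowSums(wn)
  lambda <- vn / (vp + vn)
  score <- function(p) {
    delta <- outer(p, p, "==")
    qp <- if (vp > 0) (sum(wp[delta]) - gamma * sum((sp %o% sp)[delta]) / vp) / vp else 0
    qn <- if (vn > 0) (sum(wn[delta]) - gamma * sum((sn %o% sn)[delta]) / vn) / vn else 0
    qp - lambda * qn
  }
  best <- -Inf; best_p <- NULL
  rgs <- integer(n)
  enumerate <- function(i, maxlab) {
    if (i > n) {
      s <- score(rgs)
      if (s > best) { best <<- s; best_p <<- rgs }
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      rgs[i] <<- lab
      enumerate(i + 1L, max(maxlab, lab))
    }
  }
  enumerate(1L, 0L)
  list(q_star = best, partition = as_partition(best_p))
}

# Partial correlation of columns i, j by regressing each on all remaining
# columns and correlating the residuals.
oracle_partial_correlation <- function(x) {
  n <- ncol(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- if (ncol(others) > 0) stats::resid(stats::lm(x[, i] ~ others))
            else x[, i] - mean(x[, i])
      rj <- if (ncol(others) > 0) stats::resid(stats::lm(x[, j] ~ others))
            else x[, j] - mean(x[, j])
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  out
}
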