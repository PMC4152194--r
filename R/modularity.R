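#' Generalized modularity of a partition on a signed network
#'
#' Scores how well a partition segregates a fully connected signed network
#' into modules. Each sign layer contributes a standard weighted modularity
#' term
#' \deqn{Q^{\pm} = \frac{1}{v^{\pm}} \sum_{ij} \left(w^{\pm}_{ij} -
#'   \gamma \frac{s^{\pm}_i s^{\pm}_j}{v^{\pm}}\right)
#'   \delta(M_i, M_j),}
#' with sums over all ordered node pairs of the zero-diagonal weight
#' matrix (the matrix convention of standard weighted modularity, under
#' which a single all-encompassing module on an all-positive network scores
#' exactly zero). The combined index makes negative weights auxiliary to
#' positive ones:
#' \deqn{Q^{*} = Q^{+} - \frac{v^{-}}{v^{+} + v^{-}} Q^{-}.}
#' High-scoring partitions keep most positive weight within modules and
#' most negative weight between modules. If the network has no negative
#' weights, `Q* = Q+` exactly; if it has no positive weights, `Q* = -Q-`.
#'
#' @param net A [signed_network()] (or coercible weight matrix).
#' @param p A partition (coerced with [as_partition()]).
#' @param gamma Resolution parameter (default 1; larger favours more,
#'   smaller modules).
#' @param negative_weighting `"asymmetric"` (default) scales the negative
#'   term by `v- / (v+ + v-)`; `"symmetric"` uses `Q+ - Q-`.
#' @return Named list `q_star`, `q_pos`, `q_neg` (the unweighted layer
#'   scores).
#' @export
modularity_score <- function(net, p, gamma = 1,
                             negative_weighting = c("asymmetric",
                                                    "symmetric")) {
  negative_weighting <- match.arg(negative_weighting)
  if (!inherits(net, "signed_network")) net <- signed_network(net)
  p <- as_partition(p)
  if (length(p) != net$n_nodes)
    stop("partition length does not match the network", call. = FALSE)
  if (net$v_pos + net$v_neg == 0)
    stop("all-zero weight matrix: modularity normalization undefined",
         call. = FALSE)
  q_pos <- layer_modularity(pmax(net$weights, 0), net$s_pos, net$v_pos,
                            unclass(p), gamma)
  q_neg <- layer_modularity(pmax(-net$weights, 0), net$s_neg, net$v_neg,
                            unclass(p), gamma)
  lambda <- switch(negative_weighting,
                   asymmetric = net$v_neg / (net$v_pos + net$v_neg),
                   symmetric = 1)
  list(q_star = q_pos - lambda * q_neg, q_pos = q_pos, q_neg = q_neg)
}

layer_modularity <- function(w, s, v, comm, gamma) {
  if (v == 0) return(0)
  within <- 0
  s_mod <- as.vector(rowsum(s, comm))
  for (u in unique(comm)) {
    idx <- comm == u
    within <- within + sum(w[idx, idx])
  }
  (within - gamma * sum(s_mod^2) / v) / v
}

#' Maximize generalized signed modularity (Louvain-type)
#'
#' Greedy multi-level optimization of [modularity_score()] adapted to
#' signed networks: node moves are accepted when they increase `Q*`,
#' computed jointly from the positive and negative weight layers; modules
#' are then agglomerated into super-nodes and the procedure repeats until
#' no gain remains. Each restart uses a seeded random node scan order
#' (ties broken at the first maximal gain in scan order, so results are
#' deterministic given the seed), and every restart's solution is refined
#' by single-node moves on the original network. The single-module and
#' all-singleton partitions are always scored as baselines, so the result
#' never falls below either. The returned `q_star` always equals
#' [modularity_score()] re-evaluated on the returned partition.
#'
#' @inheritParams modularity_score
#' @param n_restarts Number of seeded restarts (default 100).
#' @param seed Integer seed.
#' @return A list of class `"modularity_result"`: `partition` (canonical),
#'   `q_star`, `q_pos`, `q_neg`, `n_restarts`, `seed`.
#' @export
maximize_modularity <- function(net, n_restarts = 100L, seed = 1L,
                                gamma = 1,
                                negative_weighting = c("asymmetric",
                                                       "symmetric")) {
  negative_weighting <- match.arg(negative_weighting)
  if (!inherits(net, "signed_network")) net <- signed_network(net)
  if (net$n_nodes < 2L) stop("need at least two nodes", call. = FALSE)
  if (n_restarts < 1L) stop("n_restarts must be >= 1", call. = FALSE)
  if (net$v_pos + net$v_neg == 0)
    stop("all-zero weight matrix: modularity undefined", call. = FALSE)

  wp <- pmax(net$weights, 0)
  wn <- pmax(-net$weights, 0)
  lambda <- switch(negative_weighting,
                   asymmetric = net$v_neg / (net$v_pos + net$v_neg),
                   symmetric = 1)
  n <- net$n_nodes
  score <- function(p) modularity_score(net, p, gamma = gamma,
                                        negative_weighting =
                                          negative_weighting)$q_star

  candidates <- list(rep(1L, n), seq_len(n))  # baselines
  restart_seeds <- derive_seeds(seed, n_restarts)
  for (rs in restart_seeds) {
    ord <- withr::with_seed(rs, sample.int(n))
    p0 <- louvain_signed(wp, wn, net$v_pos, net$v_neg, lambda, gamma, ord)
    p0 <- local_moves(wp, wn, net$v_pos, net$v_neg, lambda, gamma,
                      p0, seq_len(n))$comm
    candidates[[length(candidates) + 1L]] <- p0
  }
  scores <- vapply(candidates, score, numeric(1))
  best <- as_partition(candidates[[which.max(scores)]])
  sc <- modularity_score(net, best, gamma = gamma,
                         negative_weighting = negative_weighting)
  structure(list(partition = best, q_star = sc$q_star, q_pos = sc$q_pos,
                 q_neg = sc$q_neg, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), gamma = gamma,
                 negative_weighting = negative_weighting),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf(
    "modularity_result: %d modules, Q* = %.4f (Q+ = %.4f, Q- = %.4f)\n",
    n_modules(x$partition), x$q_star, x$q_pos, x$q_neg))
  invisible(x)
}

# One full Louvain run: local moves + agglomeration until no further
# reduction in the number of communities. wp/wn are the sign-layer weight
# matrices of the ORIGINAL network; v_pos/v_neg/lambda stay fixed across
# levels (the objective is always the original network's Q*).
louvain_signed <- function(wp, wn, v_pos, v_neg, lambda, gamma, order) {
  n <- nrow(wp)
  membership <- seq_len(n)        # original node -> current community
  ap <- wp; an <- wn
  level_order <- order
  repeat {
    res <- local_moves(ap, an, v_pos, v_neg, lambda, gamma,
                       seq_len(nrow(ap)), level_order)
    comm <- match(res$comm, unique(res$comm))
    membership <- comm[membership]
    k <- max(comm)
    if (k == nrow(ap)) break
    ap <- rowsum(t(rowsum(ap, comm)), comm)
    an <- rowsum(t(rowsum(an, comm)), comm)
    level_order <- seq_len(k)
  }
  membership
}

# Sweep single-node moves until a full pass makes no move. Self-loops on
# the diagonal (from agglomeration) are handled by the all-pairs matrix
# convention: a node's strength includes its self-loop, and the self-loop
# plus own null term are community-invariant, so communities are compared
# by k_{i->c} - gamma * s_i * S_c / v per layer (S_c excluding i).
local_moves <- function(ap, an, v_pos, v_neg, lambda, gamma, comm, order) {
  n <- nrow(ap)
  comm <- as.integer(comm)
  sp <- rowSums(ap)
  sn <- rowSums(an)
  cp <- if (v_pos > 0) 2 / v_pos else 0
  cn <- if (v_neg > 0) 2 * lambda / v_neg else 0
  sp_tot <- tabulate_weighted(comm, sp, n)
  sn_tot <- tabulate_weighted(comm, sn, n)
  moved_any <- FALSE
  for (sweep in seq_len(200L)) {
    moved <- FALSE
    for (i in order) {
      a <- comm[i]
      kp <- tabulate_weighted(comm, ap[, i], n)
      kn <- tabulate_weighted(comm, an[, i], n)
      # exclude i's own contribution when evaluating its current community
      kp[a] <- kp[a] - ap[i, i]
      kn[a] <- kn[a] - an[i, i]
      spx <- sp_tot; spx[a] <- spx[a] - sp[i]
      snx <- sn_tot; snx[a] <- snx[a] - sn[i]
      g <- if (cp > 0) cp * (kp - gamma * sp[i] * spx / v_pos) else numeric(n)
      if (cn > 0) g <- g - cn * (kn - gamma * sn[i] * snx / v_neg)
      # unused labels score 0 naturally: moving there makes i a singleton
      b <- which.max(g)
      if (b != a && g[b] > g[a] + 1e-12) {
        comm[i] <- b
        sp_tot[a] <- sp_tot[a] - sp[i]; sp_tot[b] <- sp_tot[b] + sp[i]
        sn_tot[a] <- sn_tot[a] - sn[i]; sn_tot[b] <- sn_tot[b] + sn[i]
        moved <- TRUE; moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(comm = comm, moved = moved_any)
}

tabulate_weighted <- function(bins, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bins)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Consensus partition over repeated runs
#'
#' Stabilizes a stochastic optimizer: builds the node co-assignment matrix
#' (fraction of input partitions placing each node pair in the same
#' module), zeroes entries below `threshold`, re-clusters the result with
#' [maximize_modularity()], and repeats until the partition is stable.
#' Unanimous inputs are returned unchanged (idempotence). If thresholding
#' removes every positive entry, no pair has consistent support and the
#' all-singleton partition is returned.
#'
#' @param partitions Non-empty list of partitions over the same nodes.
#' @param threshold Co-assignment fraction in (0, 1) below which support is
#'   discarded (default 0.5).
#' @param n_restarts Restarts per re-clustering step (default 20).
#' @param seed Integer seed.
#' @return A partition.
#' @export
consensus_partition <- function(partitions, threshold = 0.5,
                                n_restarts = 20L, seed = 1L) {
  if (length(partitions) < 1L)
    stop("need at least one partition", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  ps <- lapply(partitions, as_partition)
  n <- length(ps[[1]])
  if (any(vapply(ps, length, 1L) != n))
    stop("partitions must all have the same length", call. = FALSE)

  coassign <- function(plist) {
    d <- matrix(0, n, n)
    for (p in plist) d <- d + outer(unclass(p), unclass(p), "==")
    d / length(plist)
  }
  d <- coassign(ps)
  current <- NULL
  for (iter in seq_len(50L)) {
    dt <- d
    dt[dt < threshold] <- 0
    diag(dt) <- 0
    if (all(dt == 0)) return(as_partition(seq_len(n)))
    p_new <- maximize_modularity(signed_network(dt), n_restarts = n_restarts,
                                 seed = seed + iter)$partition
    if (!is.null(current) && same_partition(p_new, current)) break
    current <- p_new
    d <- coassign(list(current))
  }
  current
}
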