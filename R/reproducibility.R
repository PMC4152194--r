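#' Normalized mutual information between two partitions
#'
#' From the contingency table of joint module-label counts, the mutual
#' information `I(P;Q)` is computed with natural logarithms and normalized
#' as `2 I / (H(P) + H(Q))` (switchable). Identical partitions score 1; if
#' either partition is trivial (one module) its entropy is 0 and the score
#' is 0 by the `0/0 := 0` convention.
#'
#' @param p,q Partitions over the same nodes.
#' @param normalize `"sum"` (default): `2I/(H(P)+H(Q))`; `"none"`: raw I
#'   in nats.
#' @return Scalar in `[0, 1]` (or raw nats).
#' @export
partition_mi <- function(p, q, normalize = c("sum", "none")) {
  normalize <- match.arg(normalize)
  p <- as_partition(p); q <- as_partition(q)
  if (length(p) != length(q))
    stop("partitions must have the same length", call. = FALSE)
  tab <- table(unclass(p), unclass(q)) / length(p)
  hp <- entropy_nats(rowSums(tab))
  hq <- entropy_nats(colSums(tab))
  joint <- entropy_nats(as.vector(tab))
  info <- hp + hq - joint
  if (normalize == "none") return(info)
  if (hp + hq == 0) return(0)
  mi <- 2 * info / (hp + hq)
  min(max(mi, 0), 1)
}

entropy_nats <- function(pr) {
  pr <- pr[pr > 0]
  -sum(pr * log(pr))
}

#' Variation of information between two partitions
#'
#' `VoI = H(P) + H(Q) - 2 I(P;Q)` (a metric on partitions), normalized by
#' `log N` so it lies in `[0, 1]`: 0 for identical partitions, 1 between
#' the all-singleton and the one-module partition.
#'
#' @inheritParams partition_mi
#' @param normalize `"logn"` (default) divides by `log N`; `"none"` gives
#'   raw nats.
#' @return Scalar in `[0, 1]` (or raw nats).
#' @export
partition_voi <- function(p, q, normalize = c("logn", "none")) {
  normalize <- match.arg(normalize)
  p <- as_partition(p); q <- as_partition(q)
  if (length(p) != length(q))
    stop("partitions must have the same length", call. = FALSE)
  tab <- table(unclass(p), unclass(q)) / length(p)
  hp <- entropy_nats(rowSums(tab))
  hq <- entropy_nats(colSums(tab))
  joint <- entropy_nats(as.vector(tab))
  info <- hp + hq - joint
  voi <- hp + hq - 2 * info
  if (normalize == "none") return(max(voi, 0))
  min(max(voi / log(length(p)), 0), 1)
}

pairwise_stats <- function(partitions) {
  n <- length(partitions)
  mi <- c(); voi <- c()
  for (a in seq_len(n - 1L))
    for (b in seq(a + 1L, n)) {
      mi <- c(mi, partition_mi(partitions[[a]], partitions[[b]]))
      voi <- c(voi, partition_voi(partitions[[a]], partitions[[b]]))
    }
  list(mi = mi, voi = voi)
}

sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0

#' Subject-level reproducibility of modular organization
#'
#' Partitions each subject's network independently, measures pairwise
#' similarity (normalized MI) and distance (normalized VoI) over all
#' unordered subject pairs, and repeats the computation on one seeded
#' weight-permutation [null_network()] per subject as the chance baseline.
#'
#' @param nets List (>= 2) of per-subject [signed_network()] or
#'   [fc_matrix()] objects.
#' @param n_restarts Optimizer restarts per subject (default 20).
#' @param seed Master seed.
#' @return A list of class `"reproducibility_report"` with `level`,
#'   `mi_mean`, `mi_sd`, `voi_mean`, `voi_sd`, the four `null_*`
#'   counterparts, `n_pairs`, and `seed`.
#' @export
subject_level_report <- function(nets, n_restarts = 20L, seed = 1L) {
  if (length(nets) < 2L) stop("need at least two subjects", call. = FALSE)
  nets <- lapply(nets, function(x)
    if (inherits(x, "signed_network")) x else signed_network(x))
  n <- length(nets)
  seeds <- derive_seeds(seed, 1L + n)
  # one shared optimizer seed for the observed partitions: identical inputs
  # then yield identical partitions, so the statistics reflect differences
  # between subjects, not optimizer randomness
  obs <- lapply(seq_len(n), function(i)
    maximize_modularity(nets[[i]], n_restarts = n_restarts,
                        seed = seeds[1])$partition)
  nulls <- lapply(seq_len(n), function(i) {
    nn <- null_network(nets[[i]], seed = seeds[1L + i])
    maximize_modularity(nn, n_restarts = n_restarts,
                        seed = seeds[1L + i])$partition
  })
  so <- pairwise_stats(obs)
  sn <- pairwise_stats(nulls)
  structure(list(level = "subject",
                 mi_mean = mean(so$mi), mi_sd = sd0(so$mi),
                 voi_mean = mean(so$voi), voi_sd = sd0(so$voi),
                 null_mi_mean = mean(sn$mi), null_mi_sd = sd0(sn$mi),
                 null_voi_mean = mean(sn$voi), null_voi_sd = sd0(sn$voi),
                 n_pairs = length(so$mi), n_randomizations = 1L,
                 seed = as.integer(seed)),
            class = "reproducibility_report")
}

#' Group-level reproducibility under repeated random splits
#'
#' Repeats `n_randomizations` times: split the subjects into `n_groups`
#' (seeded), average FC within each group, partition each group-mean
#' network, and record MI/VoI for every group pair. Statistics are pooled
#' over group pairs and randomizations. A parallel branch permutes each
#' group-mean network's weights ([null_network()]) before partitioning,
#' giving the chance baseline.
#'
#' @param matrices List of per-subject [fc_matrix()].
#' @param n_groups Number of groups per split (default 4).
#' @param n_randomizations Number of random splits (default 1000).
#' @param n_restarts Optimizer restarts per group partition (default 20).
#' @param seed Master seed.
#' @return A `"reproducibility_report"` with `level = "group"`.
#' @export
group_randomization_report <- function(matrices, n_groups = 4L,
                                       n_randomizations = 1000L,
                                       n_restarts = 20L, seed = 1L) {
  if (n_randomizations < 1L)
    stop("n_randomizations must be >= 1", call. = FALSE)
  seeds <- derive_seeds(seed, n_randomizations)
  mi <- voi <- null_mi <- null_voi <- c()
  for (k in seq_len(n_randomizations)) {
    res <- one_group_randomization(matrices, n_groups, n_restarts, seeds[k])
    mi <- c(mi, res$obs$mi); voi <- c(voi, res$obs$voi)
    null_mi <- c(null_mi, res$null$mi); null_voi <- c(null_voi, res$null$voi)
  }
  structure(list(level = "group",
                 mi_mean = mean(mi), mi_sd = sd0(mi),
                 voi_mean = mean(voi), voi_sd = sd0(voi),
                 null_mi_mean = mean(null_mi), null_mi_sd = sd0(null_mi),
                 null_voi_mean = mean(null_voi), null_voi_sd = sd0(null_voi),
                 n_pairs = length(mi),
                 n_randomizations = as.integer(n_randomizations),
                 seed = as.integer(seed)),
            class = "reproducibility_report")
}

# One split -> group means -> observed and null partitions -> pair stats.
# Observed group partitions share one optimizer seed (identical group means
# then give identical partitions); null branches are seeded per group.
one_group_randomization <- function(matrices, n_groups, n_restarts, seed) {
  sub_seeds <- derive_seeds(seed, 2L + n_groups)
  assignment <- split_groups(length(matrices), n_groups, sub_seeds[1])
  group_nets <- lapply(seq_len(n_groups), function(g)
    signed_network(mean_fc(matrices[assignment == g])$mean))
  obs <- lapply(seq_len(n_groups), function(g)
    maximize_modularity(group_nets[[g]], n_restarts = n_restarts,
                        seed = sub_seeds[2])$partition)
  nulls <- lapply(seq_len(n_groups), function(g) {
    nn <- null_network(group_nets[[g]], seed = sub_seeds[2L + g])
    maximize_modularity(nn, n_restarts = n_restarts,
                        seed = sub_seeds[2L + g])$partition
  })
  list(obs = pairwise_stats(obs), null = pairwise_stats(nulls),
       assignment = assignment)
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("reproducibility_report (%s level, %d pairs):\n",
              x$level, x$n_pairs))
  cat(sprintf("  MI  %.3f +/- %.3f  (null %.3f +/- %.3f)\n",
              x$mi_mean, x$mi_sd, x$null_mi_mean, x$null_mi_sd))
  cat(sprintf("  VoI %.3f +/- %.3f  (null %.3f +/- %.3f)\n",
              x$voi_mean, x$voi_sd, x$null_voi_mean, x$null_voi_sd))
  invisible(x)
}
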