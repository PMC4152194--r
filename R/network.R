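#' Signed weighted network
#'
#' Wraps a symmetric zero-diagonal weight matrix and precomputes the
#' per-node signed graph measures: positive/negative degree (counts of
#' positive/negative connections), positive/negative strength (sums of
#' absolute weights over each sign), and the network totals `v_pos`,
#' `v_neg`. Totals and strengths follow the ordered-pair (double-counting)
#' convention: `v_pos` equals twice the positive upper-triangular sum, and
#' `sum(s_pos)` equals `v_pos`.
#'
#' @param weights Symmetric numeric matrix; diagonal forced to zero. An
#'   [fc_matrix()] is accepted.
#' @return A list of class `"signed_network"` with elements `weights`,
#'   `roi_labels`, `d_pos`, `d_neg`, `s_pos`, `s_neg`, `v_pos`, `v_neg`,
#'   `n_nodes`, `n_edges`.
#' @export
signed_network <- function(weights) {
  labels <- NULL
  if (inherits(weights, "fc_matrix")) {
    labels <- weights$roi_labels
    weights <- weights$z
  }
  assert_square_symmetric(weights, "weight matrix")
  diag(weights) <- 0
  n <- nrow(weights)
  if (is.null(labels)) labels <- rownames(weights) %||% paste0("ROI", seq_len(n))
  wp <- pmax(weights, 0)
  wn <- pmax(-weights, 0)
  structure(list(weights = weights,
                 roi_labels = as.character(labels),
                 n_nodes = n,
                 n_edges = n * (n - 1L) / 2L,
                 d_pos = rowSums(weights > 0),
                 d_neg = rowSums(weights < 0),
                 s_pos = rowSums(wp),
                 s_neg = rowSums(wn),
                 v_pos = sum(wp),
                 v_neg = sum(wn)),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("signed_network:", x$n_nodes, "nodes,", x$n_edges, "edges",
      sprintf("(v+ = %.3f, v- = %.3f)\n", x$v_pos, x$v_neg))
  invisible(x)
}

#' Weight-permutation null network
#'
#' Destroys community structure while preserving the global weight
#' distribution exactly: the upper-triangular weights are permuted
#' uniformly at random (seeded) and mirrored back to symmetry. The weight
#' multiset — hence `v_pos` and `v_neg` — is conserved; only the placement
#' of weights changes.
#'
#' @param net A [signed_network()] (or coercible weight matrix).
#' @param seed Integer seed.
#' @return A new [signed_network()].
#' @export
null_network <- function(net, seed) {
  if (!inherits(net, "signed_network")) net <- signed_network(net)
  w <- net$weights
  ut <- which(upper.tri(w))
  vals <- w[ut]
  perm <- withr::with_seed(as.integer(seed), sample.int(length(vals)))
  nullw <- matrix(0, net$n_nodes, net$n_nodes)
  nullw[ut] <- vals[perm]
  nullw <- nullw + t(nullw)
  dimnames(nullw) <- dimnames(w)
  signed_network(nullw)
}
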