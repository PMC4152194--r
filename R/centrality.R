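#' Per-node signed strengths
#'
#' `s_pos[i]` is the sum of positive connection weights of node i;
#' `s_neg[i]` the sum of absolute negative connection weights.
#'
#' @param net A [signed_network()] (or coercible weight matrix).
#' @return List with numeric vectors `s_pos`, `s_neg`.
#' @export
signed_strengths <- function(net) {
  if (!inherits(net, "signed_network")) net <- signed_network(net)
  list(s_pos = net$s_pos, s_neg = net$s_neg)
}

# Node-level rescaling of the negative contribution: the share of a node's
# total absolute strength carried by its negative connections. The "global"
# alternative uses the network-wide share v- / (v+ + v-) for every node.
negative_share <- function(s_pos, s_neg, scale = c("node", "global")) {
  scale <- match.arg(scale)
  if (scale == "global") {
    tot <- sum(s_pos) + sum(s_neg)
    if (tot == 0) return(rep(0, length(s_pos)))
    return(rep(sum(s_neg) / tot, length(s_pos)))
  }
  tot <- s_pos + s_neg
  ifelse(tot > 0, s_neg / tot, 0)
}

#' Generalized strength
#'
#' Combines the sign layers so that positive connections dominate:
#' `s* = s+ - (s- / (s+ + s-)) * s-`. The rescaling factor is the node's
#' negative strength share, so a node with no negative connections keeps
#' `s* = s+`, and a purely negative node gets `s* = -s-`. Nodes with zero
#' total strength get `s* = 0`.
#'
#' @param s_pos,s_neg Nonnegative strength vectors (from
#'   [signed_strengths()]).
#' @param scale `"node"` (default) rescales by each node's own negative
#'   share; `"global"` uses the network-wide share `v- / (v+ + v-)`.
#' @return Numeric vector `s_star`.
#' @export
generalized_strength <- function(s_pos, s_neg, scale = c("node", "global")) {
  stopifnot(length(s_pos) == length(s_neg),
            all(s_pos >= 0), all(s_neg >= 0))
  s_pos - negative_share(s_pos, s_neg, scale) * s_neg
}

#' Diversity of a node's strength across modules
#'
#' For each sign layer, a node's strength is distributed over the modules
#' of a partition; the diversity is the normalized Shannon entropy of that
#' distribution, `h = -(1/log m) * sum_u p(u) log p(u)` with
#' `p(u) = s_i(u) / s_i` and the convention `0 log 0 = 0`. It is 0 when
#' all strength concentrates in one module and 1 when spread evenly over
#' all m modules (any logarithm base cancels under the normalization).
#' With a single module, or zero strength in a layer, h is defined as 0.
#' The combined index again makes negatives auxiliary:
#' `h* = h+ - (s- / (s+ + s-)) * h-`.
#'
#' @param net A [signed_network()] (or coercible weight matrix).
#' @param p A partition over the network's nodes.
#' @param scale Negative-share convention, as in [generalized_strength()].
#' @return List of numeric vectors `h_pos`, `h_neg`, `h_star`.
#' @export
diversity <- function(net, p, scale = c("node", "global")) {
  scale <- match.arg(scale)
  if (!inherits(net, "signed_network")) net <- signed_network(net)
  p <- as_partition(p)
  if (length(p) != net$n_nodes)
    stop("partition length does not match the network", call. = FALSE)
  m <- n_modules(p)
  h_layer <- function(w) {
    if (m == 1L) return(rep(0, net$n_nodes))
    s_mod <- t(rowsum(t(w), unclass(p)))       # node x module strengths
    s_tot <- rowSums(s_mod)
    pr <- s_mod / ifelse(s_tot > 0, s_tot, 1)
    plogp <- ifelse(pr > 0, pr * log(pr), 0)
    h <- -rowSums(plogp) / log(m)
    ifelse(s_tot > 0, h, 0)
  }
  h_pos <- h_layer(pmax(net$weights, 0))
  h_neg <- h_layer(pmax(-net$weights, 0))
  h_star <- h_pos - negative_share(net$s_pos, net$s_neg, scale) * h_neg
  list(h_pos = h_pos, h_neg = h_neg, h_star = h_star)
}

#' Classify network hubs
#'
#' A node is a hub when its generalized strength and generalized diversity
#' are simultaneously strictly above the respective means across all nodes.
#'
#' @param s_star,h_star Numeric vectors of generalized strength/diversity.
#' @return Logical hub flags.
#' @export
classify_hubs <- function(s_star, h_star) {
  stopifnot(length(s_star) == length(h_star), length(s_star) >= 2L)
  s_star > mean(s_star) & h_star > mean(h_star)
}

#' Full per-node centrality profile
#'
#' Computes signed strengths, generalized strength, the three diversity
#' coefficients, and hub flags on one network + partition, as a table
#' sorted by descending generalized strength.
#'
#' @inheritParams diversity
#' @return A data.frame with columns `roi`, `s_pos`, `s_neg`, `s_star`,
#'   `h_pos`, `h_neg`, `h_star`, `is_hub`, ordered by decreasing `s_star`.
#' @export
centrality_profile <- function(net, p, scale = c("node", "global")) {
  scale <- match.arg(scale)
  if (!inherits(net, "signed_network")) net <- signed_network(net)
  s <- signed_strengths(net)
  s_star <- generalized_strength(s$s_pos, s$s_neg, scale)
  h <- diversity(net, p, scale)
  out <- data.frame(roi = net$roi_labels,
                    s_pos = s$s_pos, s_neg = s$s_neg, s_star = s_star,
                    h_pos = h$h_pos, h_neg = h$h_neg, h_star = h$h_star,
                    is_hub = classify_hubs(s_star, h$h_star),
                    stringsAsFactors = FALSE)
  out[order(-out$s_star), , drop = FALSE]
}
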