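test_that("signed network derives degrees, strengths and totals correctly", {
  w <- rbind(c(0, 0.5, -0.2), c(0.5, 0, 0), c(-0.2, 0, 0))
  net <- signed_network(w)
  expect_equal(net$n_edges, 3L)
  expect_equal(net$d_pos, c(1, 1, 0))
  expect_equal(net$d_neg, c(1, 0, 1))
  expect_equal(net$s_pos, c(0.5, 0.5, 0))
  expect_equal(net$s_neg, c(0.2, 0, 0.2))
  # double-counting convention: totals are twice the upper-triangular sums
  expect_equal(net$v_pos, 1.0)
  expect_equal(net$v_neg, 0.4)
  expect_equal(sum(net$s_pos), net$v_pos)
})

test_that("one all-encompassing module on a positive network scores zero", {
  set.seed(2)
  w <- abs(random_signed_weights(7))
  sc <- modularity_score(signed_network(w), rep(1, 7))
  expect_equal(sc$q_star, 0, tolerance = 1e-12)
  expect_equal(sc$q_pos, 0, tolerance = 1e-12)
})

test_that("two disjoint positive cliques score Q* = 0.5 under the true split", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  sc <- modularity_score(signed_network(w), c(1, 1, 2, 2))
  expect_equal(sc$q_star, 0.5, tolerance = 1e-12)
})

test_that("modularity score equals the double-loop oracle on random signed networks", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    w <- random_signed_weights(n)
    p <- random_partition(n, 4)
    expect_equal(modularity_score(signed_network(w), p)$q_star,
                 oracle_modularity(w, p), tolerance = 1e-12)
  }
})

test_that("modularity score rejects degenerate inputs", {
  expect_error(modularity_score(signed_network(matrix(0, 3, 3)), c(1, 1, 2)),
               "all-zero")
  expect_error(modularity_score(signed_network(random_signed_weights(4)),
                                c(1, 2)), "length")
})

test_that("modularity is invariant under uniform positive weight rescaling", {
  set.seed(13)
  w <- random_signed_weights(9)
  p <- random_partition(9, 3)
  a <- modularity_score(signed_network(w), p)
  b <- modularity_score(signed_network(w * 7.3), p)
  expect_equal(a$q_star, b$q_star, tolerance = 1e-12)
})

test_that("all-negative networks reduce to Q* = -Q-", {
  set.seed(17)
  w <- -abs(random_signed_weights(6))
  p <- random_partition(6, 3)
  sc <- modularity_score(signed_network(w), p)
  expect_equal(sc$q_pos, 0)
  expect_equal(sc$q_star, -sc$q_neg, tolerance = 1e-12)
})

test_that("high-Q* partitions keep positive weight within and negative weight between modules", {
  net <- signed_network(default_mean_fc()$mean)
  res <- maximize_modularity(net, n_restarts = 30, seed = 3)
  delta <- outer(as.integer(res$partition), as.integer(res$partition), "==")
  wp <- pmax(net$weights, 0)
  wn <- pmax(-net$weights, 0)
  pos_within <- sum(wp[delta]) / sum(wp)
  neg_within <- sum(wn[delta]) / sum(wn)
  within_pairs <- (sum(delta) - net$n_nodes) / (net$n_nodes^2 - net$n_nodes)
  # positive weight concentrates within modules far beyond the share of
  # within-module pairs; negative weight concentrates between modules
  expect_gt(pos_within, within_pairs)
  expect_lt(neg_within, pos_within)
  expect_lt(neg_within, 0.5)
})

test_that("the optimizer attains the exhaustive-enumeration optimum on small networks", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(5:7, 1)
    w <- random_signed_weights(n)
    res <- maximize_modularity(signed_network(w), n_restarts = 20, seed = rep)
    oracle <- oracle_best_partition(w)
    expect_equal(res$q_star, oracle$q_star, tolerance = 1e-10)
  }
})

test_that("optimizer result is equivariant to node permutations", {
  set.seed(23)
  w <- random_signed_weights(12)
  perm <- sample(12)
  res1 <- maximize_modularity(signed_network(w), n_restarts = 30, seed = 5)
  res2 <- maximize_modularity(signed_network(w[perm, perm]),
                              n_restarts = 30, seed = 5)
  expect_equal(res2$q_star, res1$q_star, tolerance = 1e-10)
  expect_true(same_partition(as.integer(res1$partition)[perm],
                             as.integer(res2$partition)))
})

test_that("optimizer never scores below the trivial baselines", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    w <- random_signed_weights(n)
    net <- signed_network(w)
    res <- maximize_modularity(net, n_restarts = 5, seed = rep)
    expect_gte(res$q_star, modularity_score(net, rep(1, n))$q_star - 1e-12)
    expect_gte(res$q_star, modularity_score(net, seq_len(n))$q_star - 1e-12)
    # returned score is reproducible by rescoring the returned partition
    expect_equal(res$q_star,
                 modularity_score(net, res$partition)$q_star,
                 tolerance = 1e-12)
  }
})

test_that("optimizer is deterministic given the seed", {
  set.seed(37)
  w <- random_signed_weights(15)
  r1 <- maximize_modularity(signed_network(w), n_restarts = 10, seed = 8)
  r2 <- maximize_modularity(signed_network(w), n_restarts = 10, seed = 8)
  expect_identical(r1$q_star, r2$q_star)
  expect_true(same_partition(r1$partition, r2$partition))
})

test_that("positive-network results agree with igraph as an independent check", {
  skip_if_not_installed("igraph")
  set.seed(43)
  w <- abs(random_signed_weights(14))
  net <- signed_network(w)
  res <- maximize_modularity(net, n_restarts = 30, seed = 2)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # same scoring function: igraph's modularity of our partition equals Q*
  expect_equal(igraph::modularity(g, as.integer(res$partition),
                                  weights = igraph::E(g)$weight),
               res$q_star, tolerance = 1e-10)
  # and our optimum is at least as good as igraph's Louvain optimum
  cl <- igraph::cluster_louvain(g)
  expect_gte(res$q_star + 1e-10,
             igraph::modularity(g, igraph::membership(cl),
                                weights = igraph::E(g)$weight))
})

test_that("mean-FC partition recovers the planted six-module structure", {
  res <- maximize_modularity(signed_network(default_mean_fc()$mean),
                             n_restarts = 100, seed = 1)
  planted <- true_partition(default_spec())
  expect_equal(n_modules(res$partition), 6L)
  expect_equal(partition_mi(res$partition, planted), 1)
})

test_that("consensus partitioning is idempotent and label-invariant", {
  p <- as_partition(c(1, 1, 2, 2, 3))
  expect_true(same_partition(consensus_partition(rep(list(p), 5)), p))
  relabelled <- list(c(1, 1, 2, 2, 3), c(7, 7, 4, 4, 9), c(2, 2, 1, 1, 5))
  expect_true(same_partition(consensus_partition(relabelled), p))
})

test_that("complementary partitions leave only intersection support", {
  # co-assignment of (1,1,2,2) and (1,2,1,2) is 0.5 everywhere off-diagonal;
  # at threshold 0.75 no pair survives, leaving singletons (>= 2 modules)
  res <- consensus_partition(list(c(1, 1, 2, 2), c(1, 2, 1, 2)),
                             threshold = 0.75)
  expect_gte(n_modules(res), 2L)
  expect_true(same_partition(res, 1:4))
})

test_that("consensus validates its threshold", {
  expect_error(consensus_partition(list(c(1, 2)), threshold = 1.2),
               "between 0 and 1")
})
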