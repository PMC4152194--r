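test_that("signed strengths split the line-graph example correctly", {
  # 3-node line: edge 1-2 at +0.5, edge 2-3 at -0.2
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- -0.2
  s <- signed_strengths(signed_network(w))
  expect_equal(s$s_pos[2], 0.5)
  expect_equal(s$s_neg[2], 0.2)
  expect_equal(s$s_pos, c(0.5, 0.5, 0))
  expect_equal(s$s_neg, c(0, 0.2, 0.2))
})

test_that("all-positive networks have zero negative strength everywhere", {
  set.seed(3)
  w <- abs(random_signed_weights(8))
  s <- signed_strengths(signed_network(w))
  expect_equal(s$s_neg, rep(0, 8))
  expect_equal(sum(s$s_pos), 2 * sum(w[upper.tri(w)]))
})

test_that("generalized strength follows the rescaled-negative formula", {
  expect_equal(generalized_strength(3, 1), 3 - (1 / 4) * 1)
  expect_equal(generalized_strength(5, 0), 5)       # no negative share
  expect_equal(generalized_strength(0, 2), -2)      # share factor = 1
  expect_equal(generalized_strength(0, 0), 0)       # zero-strength node
  # vectorized
  expect_equal(generalized_strength(c(3, 5, 0), c(1, 0, 2)),
               c(2.75, 5, -2))
})

test_that("generalized strength reduces to plain strength on positive networks", {
  set.seed(9)
  w <- abs(random_signed_weights(10))
  net <- signed_network(w)
  s <- signed_strengths(net)
  expect_equal(generalized_strength(s$s_pos, s$s_neg), rowSums(w))
})

test_that("diversity hits the entropy landmarks", {
  # star node 1 connected into a single foreign module -> h_pos = 0
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 1
  p <- c(1, 2, 2, 3, 3)
  h <- diversity(signed_network(w), p)
  expect_equal(h$h_pos[1], 0)

  # equal strength in each of the m = 3 modules -> h_pos = 1
  w2 <- matrix(0, 4, 4)
  w2[1, 2:4] <- w2[2:4, 1] <- 1
  h2 <- diversity(signed_network(w2), c(1, 1, 2, 3))
  expect_equal(h2$h_pos[1], 1)

  # hand-evaluated mixed case: strengths (2,1,1) over m = 4 modules
  w3 <- matrix(0, 7, 7)
  w3[1, 2] <- w3[2, 1] <- 2   # module 2
  w3[1, 3] <- w3[3, 1] <- 1   # module 3
  w3[1, 4] <- w3[4, 1] <- 1   # module 4
  p3 <- c(1, 2, 3, 4, 1, 1, 1)
  h3 <- diversity(signed_network(w3), p3)
  expected <- -(0.5 * log(0.5) + 2 * (0.25 * log(0.25))) / log(4)
  expect_equal(h3$h_pos[1], expected, tolerance = 1e-12)
  expect_equal(expected, 0.75, tolerance = 0.01)
})

test_that("diversity handles single-module and zero-strength degenerate cases", {
  set.seed(15)
  w <- random_signed_weights(6)
  h1 <- diversity(signed_network(w), rep(1, 6))
  expect_equal(h1$h_pos, rep(0, 6))
  expect_equal(h1$h_star, rep(0, 6))
  wp <- abs(w)  # no negative layer
  h2 <- diversity(signed_network(wp), random_partition(6, 3))
  expect_equal(h2$h_neg, rep(0, 6))
  expect_equal(h2$h_star, h2$h_pos)
  expect_error(diversity(signed_network(w), c(1, 2)), "length")
})

test_that("diversity is invariant to module relabelling", {
  set.seed(25)
  w <- random_signed_weights(9)
  p <- c(1, 1, 2, 2, 3, 3, 1, 2, 3)
  q <- c(9, 9, 4, 4, 7, 7, 9, 4, 7)  # same grouping, different labels
  expect_equal(diversity(signed_network(w), p),
               diversity(signed_network(w), q))
})

test_that("hub classification uses strict above-mean on both measures", {
  expect_equal(classify_hubs(rep(1, 5), rep(1, 5)), rep(FALSE, 5))
  s <- c(10, 1, 1, 1, 1); h <- c(0.9, 0.1, 0.1, 0.1, 0.1)
  expect_equal(classify_hubs(s, h), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # above-mean strength but below-mean diversity is not a hub
  s2 <- c(10, 8, 1, 1, 1); h2 <- c(0.9, 0.1, 0.5, 0.5, 0.5)
  expect_equal(classify_hubs(s2, h2)[2], FALSE)
  expect_equal(classify_hubs(s2, h2)[1], TRUE)
})

test_that("hub set is invariant to uniform positive weight rescaling", {
  set.seed(33)
  w <- random_signed_weights(12)
  p <- random_partition(12, 4)
  prof1 <- centrality_profile(signed_network(w), p)
  prof2 <- centrality_profile(signed_network(w * 4.2), p)
  expect_equal(prof1$is_hub, prof2$is_hub)
  expect_equal(prof1$roi, prof2$roi)   # same descending-strength order
  expect_equal(prof2$s_star, prof1$s_star * 4.2, tolerance = 1e-12)
  expect_equal(prof1$h_star, prof2$h_star, tolerance = 1e-12)
})

test_that("centrality profile is a sorted table with consistent flags", {
  net <- signed_network(default_mean_fc()$mean)
  res <- maximize_modularity(net, n_restarts = 20, seed = 2)
  prof <- centrality_profile(net, res$partition)
  expect_equal(nrow(prof), 36L)
  expect_true(!is.unsorted(rev(prof$s_star)))
  expect_true(all(prof$h_pos >= 0 & prof$h_pos <= 1))
  expect_true(all(prof$h_neg >= 0 & prof$h_neg <= 1))
  expect_gt(sum(prof$is_hub), 0)
  expect_lt(sum(prof$is_hub), 36)
})
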