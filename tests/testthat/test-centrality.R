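make_net <- function(w, comm = NULL) {
  p <- nrow(w)
  network_model(w, labels = paste0("N", seq_len(p)), communities = comm)
}

test_that("strength and expected influence are signed/unsigned row sums", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- -0.5
  w[2, 3] <- w[3, 2] <- 0.3
  net <- make_net(w)
  expect_equal(unname(node_strength(net)), c(1.0, 0.8, 0.8, 0))
  expect_equal(unname(expected_influence(net)), c(0, 0.8, -0.2, 0))
  # isolated node
  expect_equal(node_strength(net)[["N4"]], 0)
  # sum of strengths counts each edge twice
  expect_equal(sum(node_strength(net)), 2 * sum(abs(w[upper.tri(w)])))
  # brute-force check on a seeded random model
  set.seed(10)
  wr <- matrix(0, 8, 8)
  wr[upper.tri(wr)] <- runif(28, -0.3, 0.3)
  wr <- wr + t(wr)
  netr <- make_net(wr)
  expect_equal(unname(node_strength(netr)), rowSums(abs(wr)))
  expect_equal(unname(expected_influence(netr)), rowSums(wr))
})

test_that("betweenness and closeness follow shortest-path conventions", {
  # 3-node path a-b-c
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  bc <- betweenness_closeness(make_net(w))
  expect_equal(bc$betweenness, c(0, 1, 0))
  # closeness = 1 / sum of 1/|w| distances
  expect_equal(bc$closeness, c(1 / (2 + 4), 1 / (2 + 2), 1 / (4 + 2)))

  # star with 4 leaves: center mediates choose(4, 2) pairs
  ws <- matrix(0, 5, 5)
  ws[1, 2:5] <- ws[2:5, 1] <- 0.4
  bs <- betweenness_closeness(make_net(ws))
  expect_equal(bs$betweenness, c(6, 0, 0, 0, 0))

  # equal-weight triangle: direct edges always shortest
  wt <- matrix(0.3, 3, 3); diag(wt) <- 0
  expect_equal(betweenness_closeness(make_net(wt))$betweenness, rep(0, 3))

  # disconnected: isolated node flagged, closeness NA
  wd <- matrix(0, 3, 3); wd[1, 2] <- wd[2, 1] <- 0.5
  bd <- betweenness_closeness(make_net(wd))
  expect_true(attr(bd, "disconnected"))
  expect_true(is.na(bd$closeness[3]))
})

test_that("bridge centrality sums cross-community edges only", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5   # within community 1
  w[1, 3] <- w[3, 1] <- 0.06  # bridges
  w[1, 4] <- w[4, 1] <- -0.04
  comm <- c(1, 1, 2, 2)
  net <- make_net(w, comm)
  br <- bridge_centrality(net)
  expect_equal(br$bridge_strength, c(0.10, 0, 0.06, 0.04))
  expect_equal(br$bridge_expected_influence, c(0.02, 0, 0.06, -0.04))
  # bridge strength + within strength = strength
  within <- node_strength(net) - br$bridge_strength
  expect_equal(br$bridge_strength + within,
               node_strength(net), ignore_attr = TRUE)
  # no cross edges -> all zero
  w0 <- matrix(0, 4, 4); w0[1, 2] <- w0[2, 1] <- 0.5
  expect_equal(bridge_centrality(make_net(w0, comm))$bridge_strength,
               rep(0, 4))
  expect_error(bridge_centrality(make_net(w, c(1, 1, 1, 1))),
               "communities")
})

test_that("centralities are invariant under relabelling", {
  set.seed(3)
  w <- matrix(0, 6, 6)
  w[upper.tri(w)] <- runif(15, 0, 0.4) * rbinom(15, 1, 0.6)
  w <- w + t(w)
  comm <- c(1, 1, 1, 2, 2, 2)
  net <- make_net(w, comm)
  perm <- c(3, 6, 1, 5, 2, 4)
  net_p <- network_model(w[perm, perm],
                         labels = paste0("N", seq_len(6))[perm],
                         communities = setNames(comm[perm],
                                                paste0("N", 1:6)[perm]))
  ct <- centrality_table(net)
  ct_p <- centrality_table(net_p)
  m <- match(ct$node, ct_p$node)
  for (col in c("strength", "expected_influence", "betweenness",
                "closeness", "bridge_strength")) {
    expect_equal(ct[[col]], ct_p[[col]][m], tolerance = 1e-12)
  }
  # z columns on request
  ctz <- centrality_table(net, standardized = TRUE)
  expect_true("strength_z" %in% names(ctz))
  expect_equal(mean(ctz$strength_z), 0, tolerance = 1e-12)
})
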