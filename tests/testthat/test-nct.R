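test_that("global strength variants reduce to triangle sums", {
  expect_equal(global_strength(network_model(matrix(0, 4, 4))), 0)
  set.seed(4)
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- runif(10, -0.3, 0.3)
  w <- w + t(w)
  net <- network_model(w)
  expect_equal(global_strength(net), sum(abs(w[upper.tri(w)])))
  expect_equal(global_strength(net, signed = TRUE), sum(w[upper.tri(w)]))
  wp <- abs(w)
  netp <- network_model(wp)
  expect_equal(global_strength(netp, signed = TRUE),
               global_strength(netp))
})

test_that("row order cannot move the observed comparison statistics", {
  spec <- small_strong_spec(seed = 5, n = 300)
  sim <- simulate_survey(spec)
  a <- sim$data
  b <- a[sample(nrow(a)), , drop = FALSE]
  res <- nct(a, b, K = 100, seed = 3, tests = c("global", "structure"))
  expect_equal(res$S, 0)
  expect_equal(res$M, 0)
  expect_true(res$p_S > 0 && res$p_S <= 1)
  expect_true(res$p_M > 0 && res$p_M <= 1)
})

test_that("nct is deterministic, null-calibrated, and order-invariant", {
  spec <- small_strong_spec(seed = 9, n = 250)
  tr <- make_block_precision(spec)
  a <- sample_ordinal(tr$omega, spec$thresholds, 250, seed = 31)
  b <- sample_ordinal(tr$omega, spec$thresholds, 250, seed = 32)
  r1 <- nct(a, b, K = 120, seed = 7, communities = tr$communities)
  r2 <- nct(a, b, K = 120, seed = 7, communities = tr$communities)
  expect_identical(r1$p_M, r2$p_M)
  expect_identical(r1$edges, r2$edges)
  # same-distribution groups should rarely reject
  expect_gt(r1$p_M, 0.01)
  # Holm adjustment never lowers a p-value
  expect_true(all(r1$edges$p_holm >= r1$edges$p - 1e-12))
  expect_true(all(r1$centrality$p_holm >= r1$centrality$p - 1e-12))
  # node-order invariance of the observed statistics
  perm <- sample(ncol(a))
  r3 <- nct(a[, perm], b[, perm], K = 120, seed = 7,
            tests = c("global", "structure"),
            communities = tr$communities[perm])
  expect_equal(r3$S, r1$S, tolerance = 1e-6)
  expect_equal(r3$M, r1$M, tolerance = 1e-6)
})

test_that("nct detects a genuinely altered edge", {
  # group b has one cross-community partial correlation raised from 0 to ~0.4
  spec_a <- generator_spec(n_nodes = c(3, 3), within_density = 0,
                           n_bridge_edges = 0, seed = 1,
                           edges = data.frame(i = 1, j = 2, weight = 0.3))
  spec_b <- generator_spec(n_nodes = c(3, 3), seed = 1,
                           edges = data.frame(i = c(1, 3), j = c(2, 5),
                                              weight = c(0.3, 0.4)))
  tra <- make_block_precision(spec_a)
  trb <- make_block_precision(spec_b)
  hits <- 0
  for (s in 1:5) {
    a <- sample_ordinal(tra$omega, spec_a$thresholds, 900, seed = 100 + s)
    b <- sample_ordinal(trb$omega, spec_b$thresholds, 900, seed = 200 + s)
    r <- nct(a, b, K = 100, seed = s, tests = c("global", "structure"))
    hits <- hits + (r$p_M < 0.05)
  }
  expect_gte(hits, 4)
})

test_that("nct validates its inputs", {
  spec <- small_strong_spec(seed = 5, n = 120)
  sim <- simulate_survey(spec)
  b <- sim$data
  colnames(b) <- rev(colnames(b))
  expect_error(nct(sim$data, b, K = 100), "same node set")
  expect_error(nct(sim$data, sim$data, K = 10), ">= 100")
})
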