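test_that("block precision matrix plants the requested structure", {
  # no edges -> identity
  spec0 <- generator_spec(within_density = 0, n_bridge_edges = 0, seed = 1)
  expect_equal(make_block_precision(spec0)$omega, diag(20))

  spec <- generator_spec(seed = 5)
  tr <- make_block_precision(spec)
  expect_equal(dim(tr$omega), c(20, 20))
  expect_gt(min(eigen(tr$omega, symmetric = TRUE,
                      only.values = TRUE)$values), 0.01)
  expect_equal(tr$communities, rep(1:2, c(7, 13)))
  # support only where planted
  support <- which(tr$omega != 0 & row(tr$omega) < col(tr$omega),
                   arr.ind = TRUE)
  planted <- tr$edges[, c("i", "j")]
  expect_setequal(paste(support[, 1], support[, 2]),
                  paste(planted$i, planted$j))
  # cross-community support only on the planted bridges
  cross <- support[tr$communities[support[, 1]] !=
                     tr$communities[support[, 2]], , drop = FALSE]
  expect_setequal(paste(cross[, 1], cross[, 2]),
                  paste(tr$bridge_edges$i, tr$bridge_edges$j))
  expect_equal(nrow(tr$bridge_edges), 2)
})

test_that("planted partial correlations are recovered from latent draws", {
  spec <- generator_spec(n_nodes = c(3, 3), seed = 9,
                         edges = data.frame(i = 1, j = 2, weight = 0.3))
  tr <- make_block_precision(spec)
  sigma <- cov2cor(solve(tr$omega))
  set.seed(11)
  z <- matrix(rnorm(50000 * 6), ncol = 6) %*% chol(sigma)
  k <- solve(cor(z))
  pc <- -k[1, 2] / sqrt(k[1, 1] * k[2, 2])
  expect_lt(abs(pc - tr$edges$weight[1]), 0.02)
})

test_that("ordinal sampling matches Gaussian cell probabilities", {
  thr <- c(-0.25, 0.5, 1.1, 1.7)
  x <- sample_ordinal(diag(4), thr, 10000, seed = 21)
  expect_true(all(x >= 0 & x <= 4))
  probs <- diff(c(0, pnorm(thr), 1))
  for (k in 0:4) {
    se <- sqrt(probs[k + 1] * (1 - probs[k + 1]) / 10000)
    expect_lt(abs(mean(x[, 2] == k) - probs[k + 1]), 3.2 * se + 1e-12)
  }
  # single cut at 0 -> balanced binary
  b <- sample_ordinal(diag(3), 0, 10000, seed = 3)
  expect_true(all(b %in% 0:1))
  expect_lt(abs(mean(b[, 1]) - 0.5), 3 * sqrt(0.25 / 10000))
  # determinism
  expect_identical(sample_ordinal(diag(4), thr, 500, seed = 7),
                   sample_ordinal(diag(4), thr, 500, seed = 7))
})

test_that("polychoric estimates recover the latent correlations at large n", {
  spec <- generator_spec(seed = 13, n_respondents = 20000)
  sim <- simulate_survey(spec)
  R <- correlation_matrix(sim$data)
  expect_equal(attr(R, "method"), "polychoric")
  sigma <- cov2cor(solve(sim$truth$omega))
  expect_lt(max(abs(R - sigma)), 0.05)
})

test_that("Ising Gibbs sampler matches closed forms", {
  # independent nodes: mean = plogis(tau)
  tau <- c(-1, 0, 0.8)
  x <- sample_ising(tau, matrix(0, 3, 3), 10000, burn_in = 200, thin = 2,
                    seed = 17)
  for (j in 1:3) {
    p <- plogis(tau[j])
    expect_lt(abs(mean(x[, j]) - p), 4 * sqrt(p * (1 - p) / 10000))
  }
  # two nodes, strong coupling: agreement beats 0.9, near the exact value
  beta <- matrix(c(0, 4, 4, 0), 2)
  y <- sample_ising(c(0, 0), beta, 10000, burn_in = 500, thin = 5,
                    seed = 19)
  agree <- mean(y[, 1] == y[, 2])
  exact <- ising2_exact(c(0, 0), 4)$agree
  expect_gt(agree, 0.9)
  expect_lt(abs(agree - exact), 0.03)
  # determinism and validation
  expect_identical(sample_ising(tau, matrix(0, 3, 3), 200, seed = 2),
                   sample_ising(tau, matrix(0, 3, 3), 200, seed = 2))
  expect_error(sample_ising(c(0, 0), matrix(c(0, 1, 0, 0), 2), 10),
               "symmetric")
})

test_that("generator spec validates thresholds and shapes", {
  expect_error(generator_spec(thresholds = c(1, 0.5)), "increasing")
  expect_error(generator_spec(weight_range = c(0.5, 0.2)))
  s <- generator_spec(n_categories = 3)
  expect_length(s$thresholds[[1]], 2)
})
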