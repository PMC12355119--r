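test_that("bivariate normal CDF agrees with the integral identity", {
  set.seed(2)
  for (i in 1:40) {
    h <- runif(1, -3, 3); k <- runif(1, -3, 3); r <- runif(1, -0.99, 0.99)
    expect_lt(abs(symptomnet:::bvn_prob_cpp(h, k, r) -
                    phi2_oracle(h, k, r)), 1e-8)
  }
  expect_equal(symptomnet:::bvn_prob_cpp(Inf, 1.3, 0.5), pnorm(1.3))
  expect_equal(symptomnet:::bvn_prob_cpp(-Inf, 1.3, 0.5), 0)
})

test_that("polychoric pair estimation is symmetric and consistent", {
  spec <- generator_spec(n_nodes = c(1, 1), n_bridge_edges = 1,
                         weight_range = c(0.5, 0.5), seed = 2,
                         n_respondents = 5000)
  sim <- simulate_survey(spec)
  x <- sim$data[, 1]; y <- sim$data[, 2]
  r1 <- polychoric_pair(x, y)
  r2 <- polychoric_pair(y, x)
  expect_lt(abs(r1$rho - r2$rho), 1e-6)
  expect_lt(abs(r1$rho - sim$truth$edges$weight[1]), 0.05)
  # identical vectors: near-perfect concordance (clamped with a warning)
  expect_warning(rid <- polychoric_pair(x, x), "clamp")
  expect_gte(rid$rho, 0.99)
  expect_error(polychoric_pair(rep(1L, 10), c(rep(1L, 9), 2L)),
               "constant")
})

test_that("auto dispatch, PSD smoothing contract and submatrix property", {
  set.seed(5)
  cont <- matrix(rnorm(300), 100, 3)
  expect_equal(attr(correlation_matrix(cont), "method"), "pearson")

  spec <- generator_spec(within_density = 0, n_bridge_edges = 0, seed = 4,
                         n_respondents = 5000)
  sim <- simulate_survey(spec)
  R <- correlation_matrix(sim$data)
  # 190 pairwise estimates with per-pair SE ~ 0.022: the null maximum
  # stays below ~3.4 standard errors
  expect_lt(max(abs(R[upper.tri(R)])), 0.075)
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  # pre-smoothing, a column subset yields the corresponding submatrix
  Rs <- correlation_matrix(sim$data[, 1:5], smooth = FALSE)
  Rfull <- correlation_matrix(sim$data, smooth = FALSE)
  expect_equal(Rs, Rfull[1:5, 1:5], ignore_attr = TRUE, tolerance = 1e-12)

  bad <- cbind(sim$data[, 1:3], const = 1L)
  expect_error(correlation_matrix(bad), "const")
})

test_that("redundancy screen flags duplicates but not sign-discordant pairs", {
  set.seed(31)
  base <- matrix(sample(0:4, 6 * 800, TRUE,
                        prob = c(.4, .25, .18, .1, .07)), 800, 6)
  dup <- cbind(base, copy = base[, 1])
  colnames(dup) <- c(paste0("V", 1:6), "copy")
  res <- suppressWarnings(goldbricker(dup))
  expect_true(any(res$redundant$node_a == "V1" &
                    res$redundant$node_b == "copy"))
  expect_equal(res$redundant$prop_significant[
    res$redundant$node_a == "V1" & res$redundant$node_b == "copy"], 0)

  # independent nodes: no candidate pairs at all
  res0 <- goldbricker(base[, 1:6])
  expect_equal(nrow(res0$redundant), 0)

  # r(a,b) = 0.8 but opposite-signed links to two other nodes: kept
  p <- 6
  sigma <- diag(p)
  sigma[1, 2] <- sigma[2, 1] <- 0.8
  sigma[1, 3] <- sigma[3, 1] <- 0.2; sigma[2, 3] <- sigma[3, 2] <- -0.2
  sigma[1, 4] <- sigma[4, 1] <- 0.2; sigma[2, 4] <- sigma[4, 2] <- -0.2
  set.seed(12)
  z <- matrix(rnorm(4000 * p), ncol = p) %*% chol(sigma)
  colnames(z) <- paste0("V", 1:p)
  res2 <- goldbricker(z)
  expect_false(any((res2$redundant$node_a == "V1" &
                      res2$redundant$node_b == "V2") |
                     (res2$redundant$node_a == "V2" &
                        res2$redundant$node_b == "V1")))
})
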