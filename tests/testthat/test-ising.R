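toy_ising_model <- function(tau, beta, labels = NULL) {
  p <- length(tau)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  dimnames(beta) <- list(labels, labels)
  structure(list(thresholds = setNames(tau, labels), couplings = beta,
                 rule = "AND", gamma = 0.25, labels = labels),
            class = "ising_model")
}

test_that("dichotomization follows the > 0 rule and flags degeneracy", {
  m <- matrix(c(0, 1, 2, 3, 4, 0, 0, 0, 4, 4), 5, 2,
              dimnames = list(NULL, c("a", "b")))
  d <- dichotomize(m)
  expect_equal(d[, "a"], c(0L, 1L, 1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(dichotomize(matrix(0, 3, 2))[1, ], c(0, 0),
               ignore_attr = TRUE)
  allfour <- matrix(4, 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(attr(dichotomize(allfour), "constant_columns"),
               c("a", "b"))
  expect_error(fit_ising(dichotomize(allfour)), "constant")
})

test_that("eLasso nulls out independent nodes and respects rule nesting", {
  set.seed(15)
  x <- matrix(rbinom(2000 * 5, 1, 0.35), ncol = 5,
              dimnames = list(NULL, paste0("V", 1:5)))
  fit <- fit_ising(x)
  off <- fit$couplings[upper.tri(fit$couplings)]
  expect_gte(mean(off == 0), 0.95)
  # AND-rule edges are a subset of OR-rule edges
  fit_or <- fit_ising(x, rule = "OR")
  expect_true(all(fit$couplings[fit$couplings != 0] != 0 &
                    fit_or$couplings[fit$couplings != 0] != 0))
  expect_true(all((fit$couplings != 0) <= (fit_or$couplings != 0)))
  expect_true(isSymmetric(fit$couplings))
})

test_that("predictability separates connected from isolated nodes", {
  beta <- matrix(0, 3, 3)
  beta[1, 2] <- beta[2, 1] <- 4
  x <- sample_ising(c(-2, -2, 0), beta, 4000, burn_in = 500, thin = 3,
                    seed = 23)
  model <- fit_ising(x)
  r2 <- nodewise_predictability(model, x)
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_gt(r2[["V1"]], 0.5)
  expect_lt(r2[["V3"]], 0.1)
})

test_that("baseline simulation reproduces the exact 2-node distribution", {
  tau <- c(-1, -0.25); b <- 1.5
  beta <- matrix(c(0, b, b, 0), 2)
  exact <- ising2_exact(tau, b)
  x <- sample_ising(tau, beta, 10000, burn_in = 1000, thin = 5, seed = 3)
  expect_lt(max(abs(colMeans(x) - exact$mean)), 0.025)
})

test_that("threshold perturbations act locally on disconnected models", {
  tau <- c(-1.5, -1.0, -0.5, 0)
  model <- toy_ising_model(tau, matrix(0, 4, 4))
  # zero perturbation with a shared seed stream changes nothing
  null <- simulate_intervention(model, 2, "amplify", sd_multiplier = 0,
                                n_sim = 2000, seed = 5)
  expect_equal(null$delta_sum_score, 0)
  # amplifying node 2 moves only node 2 beyond Monte-Carlo error
  amp <- simulate_intervention(model, 2, "amplify", n_sim = 20000,
                               burn_in = 500, seed = 7)
  dp <- attr(amp, "delta_prevalence")
  shift <- 2 * sd(tau)
  expected <- plogis(tau[2] + shift) - plogis(tau[2])
  expect_lt(abs(dp[["V2"]] - expected), 0.03)
  expect_lt(max(abs(dp[c("V1", "V3", "V4")])), 0.02)
  expect_lt(abs(amp$delta_sum_score - dp[["V2"]]), 0.04)
})

test_that("amplify and attenuate push sum scores in opposite directions", {
  beta <- matrix(0.6, 4, 4); diag(beta) <- 0
  model <- toy_ising_model(c(-2, -1.5, -1, -0.5), beta)
  sims <- simulate_all_interventions(model, n_sim = 6000, burn_in = 500,
                                     seed = 11)
  df <- as.data.frame(sims)
  for (v in model$labels) {
    up <- df$delta_sum_score[df$node == v & df$direction == "amplify"]
    down <- df$delta_sum_score[df$node == v & df$direction == "attenuate"]
    expect_gt(up, 0)
    expect_lt(down, 0)
  }
  # determinism of the full sweep
  sims2 <- simulate_all_interventions(model, n_sim = 6000, burn_in = 500,
                                      seed = 11)
  expect_identical(as.data.frame(sims), as.data.frame(sims2))
})

test_that("target ranking orders hubs first and flags candidates", {
  # node 1 is a hub with strong positive couplings; low baseline
  # activation keeps the chains away from saturation
  beta <- matrix(0, 4, 4)
  beta[1, 2:4] <- beta[2:4, 1] <- 2
  model <- toy_ising_model(c(-2, -1.6, -1.4, -1.2), beta)
  hub_first <- 0
  for (s in 1:10) {
    sims <- simulate_all_interventions(model, n_sim = 20000,
                                       burn_in = 500, seed = 100 + s)
    rk <- rank_targets(sims)
    hub_first <- hub_first +
      (rk$alleviation$node[1] == "V1") + (rk$aggravation$node[1] == "V1")
  }
  expect_gte(hub_first, 18)
  sims <- simulate_all_interventions(model, n_sim = 5000, burn_in = 500,
                                     seed = 101)
  rk <- rank_targets(sims, aggravation_threshold = 0.01,
                     alleviation_threshold = 0.1)
  expect_equal(rk$aggravation$rank, 1:4)
  expect_equal(sum(abs(rk$alleviation$relative_influence)), 100,
               tolerance = 1e-9)
  expect_true(is.logical(rk$aggravation$candidate))
})

test_that("2-node Ising parameters are recovered from simulated data", {
  beta <- matrix(c(0, 1, 1, 0), 2)
  x <- sample_ising(c(-0.5, -0.5), beta, 5000, burn_in = 2000, thin = 5,
                    seed = 29)
  fit <- fit_ising(x)
  expect_lt(abs(fit$couplings[1, 2] - 1), 0.25)
  expect_lt(max(abs(fit$thresholds + 0.5)), 0.25)
})
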