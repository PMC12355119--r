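test_that("instrument scoring hits the documented bounds and reverse rule", {
  pcs <- pcs_definition()
  all4 <- matrix(4L, 3, 13, dimnames = list(NULL, pcs$items))
  expect_equal(score_scale(pcs, all4)$total, rep(52, 3))
  expect_equal(score_scale(pcs, all4 * 0L)$total, rep(0, 3))

  fcri <- fcri_definition()
  zeros <- matrix(0L, 2, 42, dimnames = list(NULL, fcri$items))
  # only the reverse-scored item contributes: 4 + 0 - 0 = 4
  expect_equal(score_scale(fcri, zeros)$total, rep(4, 2))
  sub <- score_scale(fcri, zeros)
  expect_equal(sub$severity, rep(4, 2))
  expect_equal(sub$triggers, rep(0, 2))
})

test_that("reverse scoring is an involution and column order is irrelevant", {
  fcri <- fcri_definition()
  m <- toy_items(10, fcri$items, seed = 4)
  s1 <- score_scale(fcri, m)
  # reversing item 13 twice restores raw data
  m2 <- m
  m2[, "fcri_13"] <- 4L - m2[, "fcri_13"]
  m2[, "fcri_13"] <- 4L - m2[, "fcri_13"]
  expect_identical(m2, m)
  # shuffled columns give identical scores
  s2 <- score_scale(fcri, m[, sample(colnames(m))])
  expect_equal(s1, s2)
})

test_that("scoring rejects bad input", {
  pcs <- pcs_definition()
  m <- toy_items(5, pcs$items[-1], seed = 2)
  expect_error(score_scale(pcs, m), "unknown item")
  m2 <- toy_items(5, pcs$items, seed = 2)
  m2[1, 1] <- 9
  expect_error(score_scale(pcs, m2), "range")
  m3 <- toy_items(5, pcs$items, seed = 2)
  m3[2, 3] <- NA
  expect_error(score_scale(pcs, m3), "missing")
})

test_that("scale definitions enforce their invariants", {
  expect_error(scale_definition("x", c("a", "b"), reverse = "z"),
               "reverse")
  expect_error(scale_definition("x", c("a", "b"),
                                subscales = list(s1 = "a", s2 = "a")),
               "overlap")
  expect_error(scale_definition("x", c("a", "b"), item_range = c(4, 0)),
               "min < max")
})

test_that("cronbach alpha matches the hand-computed formula", {
  # fixed 4x2 toy matrix, alpha evaluated by hand from variances
  m <- matrix(c(1, 2, 3, 0, 2, 3, 4, 4), 4, 2)
  hand <- 2 / 1 * (1 - (var(m[, 1]) + var(m[, 2])) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), hand)

  # identical duplicated columns -> alpha = 1
  dup <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(cronbach_alpha(dup), 1)

  # two independent items: alpha -> 0 for large n
  set.seed(8)
  ind <- cbind(sample(0:4, 8000, TRUE), sample(0:4, 8000, TRUE))
  expect_lt(abs(cronbach_alpha(ind)), 0.08)

  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero")
  expect_error(cronbach_alpha(m[, 1, drop = FALSE]), "2 items")
})

test_that("network sample-size rule reproduces the parameter count", {
  r <- network_sample_size(20, 0)
  expect_equal(r$threshold_params, 20)
  expect_equal(r$pairwise_params, 190)
  expect_equal(r$minimum_n, 210)
  expect_equal(network_sample_size(20, 0.20)$required_n, 263)
  expect_equal(network_sample_size(2, 0)$minimum_n, 3)
  for (p in c(2, 5, 13, 40)) {
    expect_equal(network_sample_size(p, 0)$minimum_n, p * (p + 1) / 2)
  }
  expect_error(network_sample_size(20, 1), "attrition")
  expect_error(network_sample_size(1), "n_nodes")
})

test_that("listwise missing-data handling reports drop percentages", {
  m <- matrix(2L, 363, 5)
  m[sample(1:363, 17), 3] <- NA
  r <- handle_missing(m)
  expect_equal(r$report$n_retained, 346)
  expect_equal(r$report$pct_dropped, 4.7)
  expect_equal(r$report$pct_retained, 95.3)

  clean <- matrix(1L, 10, 4)
  expect_identical(handle_missing(clean)$data, clean)

  clean[4, 2] <- NA
  r2 <- handle_missing(clean)
  expect_equal(r2$report$n_retained, 9)
  expect_equal(r2$report$pct_dropped, 10.0)

  expect_error(handle_missing(matrix(NA_integer_, 3, 2)), "all respondents")
})

test_that("node matrix builds the 20-node layout with communities", {
  fcri <- fcri_definition(); pcs <- pcs_definition()
  m <- cbind(toy_items(25, fcri$items, seed = 5),
             toy_items(25, pcs$items, seed = 6))
  nodes <- build_node_matrix(m)
  expect_equal(colnames(nodes), c(paste0("F", 1:7), paste0("P", 1:13)))
  comm <- attr(nodes, "communities")
  expect_equal(as.integer(table(comm)), c(7, 13))
  # F2 is the severity dimension, reverse item included
  expect_equal(nodes[, "F2"],
               rowSums(m[, fcri$subscales$severity]) - 2 * m[, "fcri_13"] + 4,
               ignore_attr = TRUE)
})
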