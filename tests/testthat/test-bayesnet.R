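test_that("hill climbing attains the exhaustive 3-node optimum", {
  dags <- all_dags_3()
  expect_length(dags, 25)
  for (s in 1:4) {
    x <- chain_data(300, seed = 40 + s)
    best_oracle <- max(vapply(dags, function(a) dag_score_oracle(x, a),
                              numeric(1)))
    fit <- hill_climb(x, restarts = 5, seed = s)
    expect_equal(fit$score, best_oracle, tolerance = 1e-6)
  }
})

test_that("score decomposability and covered-edge equivalence hold", {
  x <- chain_data(400, seed = 3)
  for (a in all_dags_3()[c(2, 9, 17, 25)]) {
    expect_equal(dag_score(x, a), dag_score_oracle(x, a),
                 tolerance = 1e-8)
  }
  # A -> B alone is a covered edge; reversing it preserves the score
  a1 <- matrix(FALSE, 3, 3); a1[1, 2] <- TRUE
  a2 <- matrix(FALSE, 3, 3); a2[2, 1] <- TRUE
  expect_equal(dag_score(x, a1), dag_score(x, a2), tolerance = 1e-9)
})

test_that("independent data yield an empty DAG, chains their skeleton", {
  set.seed(77)
  noise <- matrix(rnorm(2000 * 4), ncol = 4,
                  dimnames = list(NULL, paste0("V", 1:4)))
  fit <- hill_climb(noise, restarts = 3, seed = 1)
  expect_equal(sum(fit$amat), 0)

  skel_hits <- 0
  for (s in 1:20) {
    x <- chain_data(2000, seed = 500 + s)
    f <- hill_climb(x, restarts = 3, seed = s)
    und <- unname(f$amat | t(f$amat))
    target <- matrix(FALSE, 3, 3)
    target[1, 2] <- target[2, 1] <- target[2, 3] <- target[3, 2] <- TRUE
    skel_hits <- skel_hits + identical(und, target)
  }
  expect_gte(skel_hits, 18)
})

test_that("bootstrap averaging retains only direction-consistent edges", {
  x <- chain_data(800, seed = 9)
  dag <- bootstrap_dag(x, B = 100, restarts = 1, seed = 5)
  # retained edges live on the true skeleton with high presence
  if (nrow(dag$edges) > 0) {
    pairs <- paste(pmin(dag$edges$from, dag$edges$to),
                   pmax(dag$edges$from, dag$edges$to))
    expect_true(all(pairs %in% c("A B", "B C")))
    expect_true(all(dag$edges$presence >= 0.85))
    expect_true(all(dag$edges$direction >= 0.75))
  }
  expect_gte(nrow(dag$edges), 1)
  # acyclic by construction
  m <- dag$amat + 0
  reach <- m
  for (i in 1:3) reach <- ((reach %*% m) > 0) | (reach > 0)
  expect_false(any(diag(reach) > 0))
  # pure noise: nothing survives a high presence threshold
  set.seed(41)
  noise <- matrix(rnorm(500 * 4), ncol = 4,
                  dimnames = list(NULL, paste0("V", 1:4)))
  dag0 <- bootstrap_dag(noise, B = 100, presence_threshold = 0.85,
                        restarts = 1, seed = 2)
  expect_equal(nrow(dag0$edges), 0)
  # determinism
  dag2 <- bootstrap_dag(x, B = 100, restarts = 1, seed = 5)
  expect_identical(dag$edges, dag2$edges)
})

test_that("Markov blanket and branching metrics match hand enumeration", {
  # chain A -> B -> C: blankets {B}, {A, C}, {B}
  chain <- matrix(FALSE, 3, 3,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  chain["A", "B"] <- chain["B", "C"] <- TRUE
  m <- dag_metrics(chain)
  expect_equal(m$mbs, 4 / 3)
  expect_equal(m$bf, 2 / 3)
  expect_equal(unname(m$blanket_size), c(1, 2, 1))
  expect_equal(m$parent_nodes, "A")

  # collider A -> C <- B: co-parents enter the blanket
  coll <- matrix(FALSE, 3, 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  coll["A", "C"] <- coll["B", "C"] <- TRUE
  mc <- dag_metrics(coll)
  expect_equal(unname(mc$blanket_size), c(2, 2, 2))
  expect_equal(mc$mbs, 2)
  expect_setequal(mc$parent_nodes, c("A", "B"))

  # empty DAG
  m0 <- dag_metrics(matrix(FALSE, 4, 4))
  expect_equal(m0$mbs, 0)
  expect_equal(m0$bf, 0)
})
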