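#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Respondents are resampled with replacement `B` times; the correlation
#' matrix and EBIC graphical lasso are re-estimated on each replicate, and
#' percentile 2.5/97.5% bounds summarize each edge's sampling
#' distribution. Replicates whose estimation fails are recorded and
#' skipped.
#'
#' @param data respondent-by-node matrix.
#' @param B bootstrap replicates (>= 100; a warning suggests >= 1000).
#' @param seed integer seed (deterministic given seed).
#' @param method,gamma,n_lambdas,lambda_min_ratio estimator settings
#'   (see [fit_network()]).
#' @return object of class `edge_bootstrap`: data.frame `edges`
#'   (`node_a`, `node_b`, `estimate`, `boot_mean`, `ci_lower`,
#'   `ci_upper`), `n_failed`, and `settings`.
#' @export
edge_ci_bootstrap <- function(data, B = 1000, seed = NULL, method = "auto",
                              gamma = 0.5, n_lambdas = 100,
                              lambda_min_ratio = 0.01) {
  data <- as_response_matrix(data)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  if (B < 1000) warning("B < 1000: bootstrap CIs may be unstable")
  n <- nrow(data)
  full <- fit_network(data, method = method, gamma = gamma,
                      n_lambdas = n_lambdas,
                      lambda_min_ratio = lambda_min_ratio)
  p <- length(full$labels)
  pairs <- upper_pairs(p)
  est <- full$weights[upper.tri(full$weights)]
  boot <- matrix(NA_real_, B, length(est))
  n_failed <- 0L
  with_seed(seed, {
    method_used <- resolve_cor_method(data, method)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      w <- tryCatch(
        fast_weights(data[idx, , drop = FALSE], method_used, gamma,
                     n_lambdas, lambda_min_ratio),
        error = function(e) NULL)
      if (is.null(w)) { n_failed <- n_failed + 1L; next }
      boot[b, ] <- w[upper.tri(w)]
    }
  })
  edges <- data.frame(
    node_a = full$labels[pairs[, 1]],
    node_b = full$labels[pairs[, 2]],
    estimate = est,
    boot_mean = colMeans(boot, na.rm = TRUE),
    ci_lower = apply(boot, 2, quantile, 0.025, na.rm = TRUE),
    ci_upper = apply(boot, 2, quantile, 0.975, na.rm = TRUE))
  structure(list(edges = edges, n_failed = n_failed, network = full,
                 settings = list(B = B, seed = seed, method = method,
                                 gamma = gamma)),
            class = "edge_bootstrap")
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat(sprintf("<edge_bootstrap> B = %d (%d failed), %d edges\n",
              x$settings$B, x$n_failed, nrow(x$edges)))
  invisible(x)
}

# Compute the requested centrality indices for one fitted network.
centrality_vector <- function(net, index) {
  switch(index,
    strength = node_strength(net),
    expected_influence = expected_influence(net),
    bridge_strength = setNames(bridge_centrality(net)$bridge_strength,
                               net$labels),
    bridge_expected_influence =
      setNames(bridge_centrality(net)$bridge_expected_influence,
               net$labels),
    betweenness = setNames(betweenness_closeness(net)$betweenness,
                           net$labels),
    closeness = setNames(betweenness_closeness(net)$closeness, net$labels),
    stop("unknown centrality index: ", index, call. = FALSE))
}

#' Correlation stability coefficient by case-dropping bootstrap
#'
#' For each drop proportion `q` in `drop_grid`, `B` subsamples retaining
#' `ceiling((1 - q) n)` respondents are drawn; the network and centrality
#' index are recomputed and correlated (Spearman by default) with the
#' full-sample values. The CS coefficient is the largest `q` such that
#' this correlation reaches `cor_threshold` in at least 95% of
#' subsamples (0 when no `q` qualifies). A CS above 0.25 is convention-
#' ally required, above 0.5 preferred. Subsample correlations that are
#' undefined (e.g. a degenerate all-zero centrality vector) count as
#' failures.
#'
#' @param data respondent-by-node matrix.
#' @param indices centrality indices to assess (see
#'   [centrality_table()]); bridge indices require a `communities`
#'   attribute on `data` or the `communities` argument.
#' @param drop_grid increasing drop proportions inside (0, 0.9].
#' @param B subsamples per drop proportion.
#' @param cor_threshold required correlation with the full sample
#'   (default 0.7).
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @param seed integer seed.
#' @param method,gamma,n_lambdas,lambda_min_ratio estimator settings.
#' @param communities optional node-to-community map.
#' @return object of class `cs_result`: named `cs` vector, the per-(q,
#'   index) pass proportions, and settings.
#' @export
cs_coefficient <- function(data, indices = "strength",
                           drop_grid = seq(0.05, 0.75, by = 0.05),
                           B = 1000, cor_threshold = 0.7,
                           cor_method = c("spearman", "pearson"),
                           seed = NULL, method = "auto", gamma = 0.5,
                           n_lambdas = 100, lambda_min_ratio = 0.01,
                           communities = attr(data, "communities")) {
  cor_method <- match.arg(cor_method)
  data <- as_response_matrix(data)
  stopifnot(all(drop_grid > 0), all(drop_grid <= 0.9),
            !is.unsorted(drop_grid))
  n <- nrow(data)
  full <- fit_network(data, method = method, gamma = gamma,
                      n_lambdas = n_lambdas,
                      lambda_min_ratio = lambda_min_ratio,
                      communities = communities)
  p <- length(full$labels)
  method_used <- resolve_cor_method(data, method)
  full_cent <- lapply(setNames(indices, indices),
                      function(i) centrality_vector(full, i))
  props <- matrix(NA_real_, length(drop_grid), length(indices),
                  dimnames = list(paste0("drop_", drop_grid), indices))
  with_seed(seed, {
    for (qi in seq_along(drop_grid)) {
      keep_n <- ceiling((1 - drop_grid[qi]) * n)
      if (keep_n < p + 1) {
        warning(sprintf("drop proportion %.2f leaves n = %d < %d; skipped",
                        drop_grid[qi], keep_n, p + 1))
        next
      }
      ok <- matrix(FALSE, B, length(indices))
      for (b in seq_len(B)) {
        idx <- sample.int(n, keep_n, replace = FALSE)
        net <- tryCatch(
          fast_model(fast_weights(data[idx, , drop = FALSE], method_used,
                                  gamma, n_lambdas, lambda_min_ratio),
                     full$labels, communities),
          error = function(e) NULL)
        if (is.null(net)) next
        for (ii in seq_along(indices)) {
          cv <- centrality_vector(net, indices[ii])
          r <- suppressWarnings(cor(full_cent[[ii]], cv,
                                    method = cor_method,
                                    use = "complete.obs"))
          ok[b, ii] <- is.finite(r) && r >= cor_threshold
        }
      }
      props[qi, ] <- colMeans(ok)
    }
  })
  cs <- vapply(seq_along(indices), function(ii) {
    qual <- which(props[, ii] >= 0.95)
    if (length(qual) == 0) 0 else max(drop_grid[qual])
  }, numeric(1))
  structure(list(cs = setNames(cs, indices), proportions = props,
                 settings = list(drop_grid = drop_grid, B = B,
                                 cor_threshold = cor_threshold,
                                 cor_method = cor_method, seed = seed,
                                 method = method, gamma = gamma)),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat("<cs_result> CS coefficients (cor >=",
      x$settings$cor_threshold, "in >= 95% of subsamples):\n")
  print(x$cs)
  invisible(x)
}
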