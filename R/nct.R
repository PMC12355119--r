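#' Global strength of a network
#'
#' Unsigned: `sum_{i<j} |w_ij|`. Signed (the global expected-influence
#' variant): `sum_{i<j} w_ij`.
#'
#' @param net a [network_model()].
#' @param signed use the signed sum.
#' @return scalar.
#' @export
global_strength <- function(net, signed = FALSE) {
  stopifnot(inherits(net, "network_model"))
  w <- net$weights[upper.tri(net$weights)]
  if (signed) sum(w) else sum(abs(w))
}

# Lean weights-only estimate used inside permutation/bootstrap loops:
# skips object construction and (for Gram-matrix methods) smoothing.
fast_weights <- function(data, method, gamma, n_lambdas, lambda_min_ratio) {
  S <- switch(method,
    spearman = spearman_cor_cpp(data),
    pearson = cor(data),
    correlation_matrix(data, method = method))
  if (anyNA(S)) stop("undefined correlations in resample", call. = FALSE)
  p <- ncol(S)
  lambda_max <- max(abs(S[upper.tri(S)]), 0)
  if (lambda_max < 1e-10) return(matrix(0, p, p))
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  ebic_path_cpp(S, nrow(data), gamma, lambdas, 1e-4, 10000L)$weights
}

# network_model without validation overhead (inputs known-good).
fast_model <- function(W, labels, communities) {
  dimnames(W) <- list(labels, labels)
  structure(list(labels = labels, weights = W, communities = communities,
                 lambda_selected = NA_real_, n = NA_integer_,
                 gamma = NA_real_),
            class = "network_model")
}

#' Permutation network comparison test
#'
#' Compares two group networks estimated by the same EBIC graphical-lasso
#' pipeline. Test statistics: `S`, the absolute difference in global
#' strength (signed/expected-influence variant by default), and `M`, the
#' maximum absolute edge-weight difference (network structure
#' invariance). The null distribution pools respondents and re-splits
#' them at the original group sizes `K` times, re-estimating both
#' networks per permutation; p-values use the add-one convention
#' `p = (1 + #{perm >= obs}) / (K + 1)` and therefore never equal 0.
#' Optional edge-level and centrality-level invariance tests are
#' Holm-corrected.
#'
#' @param data_a,data_b respondent-by-node matrices over the same nodes.
#' @param K number of permutations (>= 100).
#' @param tests subset of `c("global", "structure", "edges",
#'   "centrality")`.
#' @param seed integer seed.
#' @param signed_global use the signed (expected influence) global
#'   strength (default `TRUE`).
#' @param centrality_indices indices for the centrality invariance test.
#' @param method,gamma,n_lambdas,lambda_min_ratio estimator settings.
#' @param communities node-to-community map (needed for bridge indices).
#' @return object of class `nct_result`.
#' @export
nct <- function(data_a, data_b, K = 1000,
                tests = c("global", "structure", "edges", "centrality"),
                seed = NULL, signed_global = TRUE,
                centrality_indices = c("strength",
                                       "bridge_expected_influence"),
                method = "auto", gamma = 0.5, n_lambdas = 100,
                lambda_min_ratio = 0.01,
                communities = attr(data_a, "communities")) {
  data_a <- as_response_matrix(data_a)
  data_b <- as_response_matrix(data_b)
  tests <- match.arg(tests, several.ok = TRUE)
  if (!identical(colnames(data_a), colnames(data_b))) {
    stop("both groups must share the same node set", call. = FALSE)
  }
  if (K < 100) stop("K must be >= 100", call. = FALSE)
  p <- ncol(data_a)
  if (!is.null(communities) && is.null(names(communities))) {
    communities <- setNames(communities, colnames(data_a))
  }
  if (nrow(data_a) < p || nrow(data_b) < p) {
    warning("a group has fewer respondents than nodes")
  }
  if (is.null(communities) ||
      length(unique(communities)) < 2) {
    centrality_indices <- setdiff(centrality_indices,
                                  c("bridge_strength",
                                    "bridge_expected_influence"))
  }
  fit1 <- function(x) {
    fit_network(x, method = method, gamma = gamma, n_lambdas = n_lambdas,
                lambda_min_ratio = lambda_min_ratio,
                communities = communities)
  }
  net_a <- fit1(data_a)
  net_b <- fit1(data_b)
  gs_a <- global_strength(net_a, signed = signed_global)
  gs_b <- global_strength(net_b, signed = signed_global)
  obs_S <- abs(gs_a - gs_b)
  diff_w <- net_a$weights - net_b$weights
  obs_edge <- diff_w[upper.tri(diff_w)]
  obs_M <- max(abs(obs_edge))
  do_cent <- "centrality" %in% tests && length(centrality_indices) > 0
  obs_cent <- if (do_cent) {
    vapply(centrality_indices, function(i) {
      abs(centrality_vector(net_a, i) - centrality_vector(net_b, i))
    }, numeric(p))
  }

  pooled <- rbind(data_a, data_b)
  n_a <- nrow(data_a)
  n_tot <- nrow(pooled)
  perm_S <- perm_M <- numeric(K)
  perm_edge_ge <- numeric(length(obs_edge))
  perm_cent_ge <- if (do_cent) matrix(0, p, length(centrality_indices))
  ut <- upper.tri(diag(p))
  with_seed(seed, {
    for (k in seq_len(K)) {
      res <- NULL
      for (attempt in 1:2) {
        idx <- sample.int(n_tot, n_a)
        res <- tryCatch({
          wa <- fast_weights(pooled[idx, , drop = FALSE], method, gamma,
                             n_lambdas, lambda_min_ratio)
          wb <- fast_weights(pooled[-idx, , drop = FALSE], method, gamma,
                             n_lambdas, lambda_min_ratio)
          list(wa = wa, wb = wb)
        }, error = function(e) NULL)
        if (!is.null(res)) break
      }
      if (is.null(res)) {
        stop("network estimation failed twice in a permutation",
             call. = FALSE)
      }
      ea <- res$wa[ut]; eb <- res$wb[ut]
      perm_S[k] <- if (signed_global) abs(sum(ea) - sum(eb)) else
        abs(sum(abs(ea)) - sum(abs(eb)))
      de <- ea - eb
      perm_M[k] <- max(abs(de))
      if ("edges" %in% tests) {
        perm_edge_ge <- perm_edge_ge + (abs(de) >= abs(obs_edge))
      }
      if (do_cent) {
        na <- fast_model(res$wa, net_a$labels, communities)
        nb <- fast_model(res$wb, net_a$labels, communities)
        pc <- vapply(centrality_indices, function(i) {
          abs(centrality_vector(na, i) - centrality_vector(nb, i))
        }, numeric(p))
        perm_cent_ge <- perm_cent_ge + (pc >= obs_cent)
      }
    }
  })
  out <- list(global_strength = c(a = gs_a, b = gs_b),
              S = obs_S,
              M = obs_M,
              p_S = (1 + sum(perm_S >= obs_S)) / (K + 1),
              p_M = (1 + sum(perm_M >= obs_M)) / (K + 1),
              networks = list(a = net_a, b = net_b),
              settings = list(K = K, seed = seed,
                              signed_global = signed_global,
                              method = method, gamma = gamma,
                              tests = tests))
  if ("edges" %in% tests) {
    pairs <- upper_pairs(p)
    praw <- (1 + perm_edge_ge) / (K + 1)
    out$edges <- data.frame(node_a = net_a$labels[pairs[, 1]],
                            node_b = net_a$labels[pairs[, 2]],
                            diff = obs_edge,
                            p = praw,
                            p_holm = p.adjust(praw, method = "holm"))
  }
  if (do_cent) {
    praw <- (1 + perm_cent_ge) / (K + 1)
    cent <- data.frame(node = rep(net_a$labels,
                                  length(centrality_indices)),
                       index = rep(centrality_indices, each = p),
                       diff = as.numeric(obs_cent),
                       p = as.numeric(praw))
    cent$p_holm <- unlist(lapply(centrality_indices, function(i) {
      p.adjust(cent$p[cent$index == i], method = "holm")
    }))
    out$centrality <- cent
  }
  structure(out, class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf("<nct_result> K = %d permutations\n", x$settings$K))
  cat(sprintf("  global strength: %.3f vs %.3f, S = %.3f, p = %.3f\n",
              x$global_strength["a"], x$global_strength["b"], x$S, x$p_S))
  cat(sprintf("  structure: M = %.3f, p = %.3f\n", x$M, x$p_M))
  invisible(x)
}
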