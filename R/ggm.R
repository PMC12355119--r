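#' Construct a network model object
#'
#' A `network_model` is a symmetric weighted partial-correlation network:
#' zero diagonal, weights in `[-1, 1]`, optional node-to-community map.
#'
#' @param weights symmetric numeric matrix with zero diagonal.
#' @param labels node labels (defaults to the matrix dimnames).
#' @param communities optional named integer vector mapping node to
#'   community.
#' @param lambda_selected,n,gamma estimation metadata (optional).
#' @return an object of class `network_model`.
#' @export
network_model <- function(weights, labels = NULL, communities = NULL,
                          lambda_selected = NA_real_, n = NA_integer_,
                          gamma = NA_real_) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  stopifnot(ncol(weights) == p)
  if (max(abs(weights - t(weights))) > 1e-8) {
    stop("weights must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(weights))) > 1e-8) {
    stop("weights must have zero diagonal", call. = FALSE)
  }
  if (max(abs(weights)) > 1 + 1e-8) {
    stop("partial correlations must lie in [-1, 1]", call. = FALSE)
  }
  labels <- labels %||% colnames(weights) %||% paste0("V", seq_len(p))
  dimnames(weights) <- list(labels, labels)
  if (!is.null(communities)) {
    if (!is.null(names(communities))) communities <- communities[labels]
    communities <- setNames(as.integer(communities), labels)
  }
  structure(list(labels = labels, weights = weights,
                 communities = communities,
                 lambda_selected = lambda_selected, n = n, gamma = gamma),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<network_model> %d nodes, %d/%d nonzero edges (%.2f%%)\n",
              length(x$labels), s$n_nonzero, s$n_possible, s$pct_nonzero))
  if (!is.na(x$lambda_selected)) {
    cat(sprintf("  lambda = %.4g (EBIC gamma = %.2g), n = %d\n",
                x$lambda_selected, x$gamma, x$n))
  }
  invisible(x)
}

#' Graphical lasso at a fixed penalty
#'
#' Maximizes `log det K - tr(SK) - lambda * sum_{i != j} |K_ij|` by block
#' coordinate descent (lasso regressions on each row/column of the
#' estimated covariance), the standard sparse inverse-covariance
#' algorithm. Convergence is declared when the maximum change in the
#' working covariance falls below `tol` times the average absolute
#' off-diagonal of `S`.
#'
#' @param S positive semi-definite correlation/covariance matrix.
#' @param lambda non-negative L1 penalty.
#' @param tol convergence tolerance (default 1e-4).
#' @param maxit maximum coordinate sweeps (default 10000).
#' @return list with `precision` (the estimate `K`), `covariance` (its
#'   working inverse), `iterations`, `converged`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-4, maxit = 10000) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), lambda >= 0)
  fit <- glasso_cpp(S, lambda, tol, as.integer(maxit))
  if (!fit$converged) {
    stop(sprintf(paste0("graphical lasso did not converge in %d sweeps ",
                        "(lambda = %g, p = %d)"),
                 maxit, lambda, nrow(S)), call. = FALSE)
  }
  dimnames(fit$theta) <- dimnames(S)
  dimnames(fit$w) <- dimnames(S)
  list(precision = fit$theta, covariance = fit$w,
       iterations = fit$iterations, converged = fit$converged)
}

#' Select a sparse network by EBIC over a graphical-lasso path
#'
#' Fits a descending log-spaced lambda path from
#' `lambda_max = max |off-diagonal of S|` down to
#' `lambda_min_ratio * lambda_max` and selects the model minimizing
#' `EBIC = -2 loglik + E log n + 4 E gamma log p`, where `E` is the number
#' of nonzero upper-triangle edges and the log-likelihood uses the
#' penalized estimate directly. Precision entries are converted to partial
#' correlations `w_ij = -K_ij / sqrt(K_ii K_jj)`.
#'
#' @param S correlation matrix (PSD; see [correlation_matrix()]).
#' @param n sample size behind `S`.
#' @param gamma EBIC hyperparameter (default 0.5; 0 recovers plain BIC).
#' @param n_lambdas path length (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of the largest
#'   (default 0.01).
#' @param communities optional node-to-community map stored on the model.
#' @param tol,maxit passed to the graphical-lasso core.
#' @return a [network_model()] with a `path` attribute (lambdas, EBIC,
#'   edge counts).
#' @export
ebic_select <- function(S, n, gamma = 0.5, n_lambdas = 100,
                        lambda_min_ratio = 0.01, communities = NULL,
                        tol = 1e-4, maxit = 10000) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (n <= p) {
    warning("sample size not larger than node count; estimates unstable")
  }
  lambda_max <- max(abs(S[upper.tri(S)]), 0)
  if (lambda_max < 1e-10) {
    net <- network_model(matrix(0, p, p,
                                dimnames = dimnames(S) %||%
                                  list(paste0("V", 1:p), paste0("V", 1:p))),
                         communities = communities,
                         lambda_selected = 0, n = as.integer(n),
                         gamma = gamma)
    attr(net, "path") <- data.frame(lambda = 0, ebic = NA, n_edges = 0)
    return(net)
  }
  if (n_lambdas < 1) stop("empty lambda path", call. = FALSE)
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  fit <- ebic_path_cpp(S, as.integer(n), gamma, lambdas, tol,
                       as.integer(maxit))
  W <- fit$weights
  dimnames(W) <- dimnames(S)
  net <- network_model(W, communities = communities,
                       lambda_selected = fit$lambda, n = as.integer(n),
                       gamma = gamma)
  net$precision <- fit$theta
  attr(net, "path") <- data.frame(lambda = lambdas,
                                  ebic = as.numeric(fit$ebic),
                                  loglik = as.numeric(fit$loglik),
                                  n_edges = as.integer(fit$n_edges))
  net
}

#' Estimate a symptom network from raw ordinal data
#'
#' Convenience wrapper: [correlation_matrix()] followed by
#' [ebic_select()]. Communities default to the data's `communities`
#' attribute when present.
#'
#' @param data respondent-by-node matrix.
#' @param method correlation method (see [correlation_matrix()]).
#' @param gamma,n_lambdas,lambda_min_ratio EBIC path settings.
#' @param communities optional node-to-community map.
#' @return a [network_model()].
#' @export
fit_network <- function(data, method = "auto", gamma = 0.5,
                        n_lambdas = 100, lambda_min_ratio = 0.01,
                        communities = attr(data, "communities")) {
  S <- correlation_matrix(data, method = method)
  ebic_select(S, n = nrow(data), gamma = gamma, n_lambdas = n_lambdas,
              lambda_min_ratio = lambda_min_ratio, communities = communities)
}

#' Summarize network density and edge weights
#'
#' @param net a [network_model()].
#' @param n_strongest number of top edges to list.
#' @return list with `n_nodes`, `n_possible`, `n_nonzero`, `n_zero`,
#'   `pct_nonzero`, `pct_zero` (percentages rounded half-up to 2
#'   decimals), `mean_abs_weight_nonzero`, `mean_abs_weight_all` (the
#'   average-weight denominator is ambiguous in common reporting, so both
#'   are given), and `strongest_edges`.
#' @export
network_summary <- function(net, n_strongest = 10) {
  stopifnot(inherits(net, "network_model"))
  p <- length(net$labels)
  w <- net$weights[upper.tri(net$weights)]
  pairs <- upper_pairs(p)
  n_possible <- p * (p - 1) / 2
  nz <- which(w != 0)
  ord <- order(abs(w), decreasing = TRUE)
  ord <- ord[abs(w[ord]) > 0]
  top <- head(ord, n_strongest)
  list(n_nodes = p,
       n_possible = n_possible,
       n_nonzero = length(nz),
       n_zero = n_possible - length(nz),
       pct_nonzero = round_half_up(length(nz) / n_possible * 100, 2),
       pct_zero = round_half_up((n_possible - length(nz)) / n_possible * 100, 2),
       mean_abs_weight_nonzero = if (length(nz) > 0) mean(abs(w[nz])) else 0,
       mean_abs_weight_all = sum(abs(w)) / n_possible,
       strongest_edges = data.frame(
         node_a = net$labels[pairs[top, 1]],
         node_b = net$labels[pairs[top, 2]],
         weight = w[top]))
}

#' Export a network as a weighted edge list
#'
#' @param net a [network_model()].
#' @param file optional path; when given, a TSV (`node_a`, `node_b`,
#'   `weight`) is written.
#' @param keep_zero include structural-zero pairs.
#' @return the edge-list data.frame (invisibly when writing).
#' @export
network_edge_list <- function(net, file = NULL, keep_zero = FALSE) {
  p <- length(net$labels)
  pairs <- upper_pairs(p)
  w <- net$weights[upper.tri(net$weights)]
  df <- data.frame(node_a = net$labels[pairs[, 1]],
                   node_b = net$labels[pairs[, 2]],
                   weight = w)
  if (!keep_zero) df <- df[df$weight != 0, , drop = FALSE]
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Export a network as GraphML with community attributes
#'
#' @param net a [network_model()].
#' @param file output path.
#' @return invisibly, the igraph object written.
#' @export
write_network_graphml <- function(net, file) {
  g <- network_igraph(net, absolute = FALSE)
  if (!is.null(net$communities)) {
    igraph::V(g)$community <- as.integer(net$communities[net$labels])
  }
  igraph::write_graph(g, file, format = "graphml")
  invisible(g)
}

# igraph view of a network model; edge attribute `weight` is the partial
# correlation (or its absolute value), `length` the 1/|w| distance.
network_igraph <- function(net, absolute = TRUE) {
  w <- net$weights
  adj <- abs(w)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(ends) > 0) {
    igraph::E(g)$signed_weight <- w[ends]
    if (!absolute) igraph::E(g)$weight <- w[ends]
    igraph::E(g)$length <- 1 / abs(w[ends])
  }
  g
}
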