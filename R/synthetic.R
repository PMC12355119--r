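#' Specification for the synthetic ordinal questionnaire generator
#'
#' Ordinal Likert responses are generated by discretizing a latent
#' zero-mean multivariate Gaussian whose precision matrix has a sparse
#' two-community block structure with a few planted cross-community
#' "bridge" edges. Defaults emulate a 20-node symptom survey: a 7-node
#' community (questionnaire dimension scores) and a 13-node community
#' (single items), 5 response categories with right-skewed marginals, and
#' a sample size matching a mid-sized oncology cohort.
#'
#' @param n_nodes_per_community two positive integers.
#' @param within_density probability that a within-community pair is
#'   connected.
#' @param n_bridge_edges number of planted cross-community edges.
#' @param weight_range positive interval from which planted partial
#'   correlations are drawn.
#' @param n_categories number of ordinal categories (responses are coded
#'   `0 .. n_categories - 1`).
#' @param thresholds latent cut points: a numeric vector (recycled per
#'   node) or a list with one strictly increasing vector per node. The
#'   default gives right-skewed, symptom-like marginals
#'   (approximately 40/28/17/10/5% across 5 categories).
#' @param n_respondents number of rows to sample.
#' @param seed integer seed; the generator is deterministic given a seed.
#' @param edges optional data.frame (`i`, `j`, `weight`) of explicit edges
#'   to plant instead of random ones (node indices into the full matrix).
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(n_nodes_per_community = c(7L, 13L),
                           within_density = 0.65,
                           n_bridge_edges = 2L,
                           weight_range = c(0.2, 0.4),
                           n_categories = 5L,
                           thresholds = NULL,
                           n_respondents = 346L,
                           seed = NULL,
                           edges = NULL) {
  stopifnot(length(n_nodes_per_community) == 2,
            all(n_nodes_per_community >= 1),
            within_density >= 0, within_density <= 1,
            n_bridge_edges >= 0,
            length(weight_range) == 2, weight_range[1] > 0,
            weight_range[1] <= weight_range[2], weight_range[2] < 1,
            n_categories >= 2, n_respondents >= 1)
  p <- sum(n_nodes_per_community)
  if (is.null(thresholds)) {
    base <- qnorm(cumsum(c(0.40, 0.28, 0.17, 0.10))) # 5-category default
    if (n_categories != 5) {
      base <- qnorm(seq_len(n_categories - 1) / n_categories)
    }
    thresholds <- rep(list(base), p)
  } else if (!is.list(thresholds)) {
    thresholds <- rep(list(thresholds), p)
  }
  stopifnot(length(thresholds) == p)
  for (t in thresholds) {
    if (length(t) != n_categories - 1 || is.unsorted(t, strictly = TRUE)) {
      stop("each threshold vector must be strictly increasing with ",
           "n_categories - 1 cut points", call. = FALSE)
    }
  }
  structure(list(n_nodes_per_community = as.integer(n_nodes_per_community),
                 within_density = within_density,
                 n_bridge_edges = as.integer(n_bridge_edges),
                 weight_range = weight_range,
                 n_categories = as.integer(n_categories),
                 thresholds = thresholds,
                 n_respondents = as.integer(n_respondents),
                 seed = seed, edges = edges),
            class = "generator_spec")
}

#' Build a sparse two-community block precision matrix
#'
#' Off-diagonal support is planted only on randomly chosen
#' within-community pairs (at `within_density`) and on `n_bridge_edges`
#' cross-community pairs. A planted partial correlation `w` for pair
#' `(i, j)` sets `Omega[i, j] = -w` on a unit diagonal. Positive
#' definiteness is enforced by scaling all off-diagonals down until the
#' smallest eigenvalue exceeds 0.01; the returned truth records the
#' realized (possibly shrunken) partial correlations.
#'
#' @param spec a [generator_spec()].
#' @return list with `omega` (precision matrix), `edges` (data.frame
#'   `i`, `j`, `weight` of realized partial correlations), `communities`
#'   (integer vector), `bridge_edges`, and `bridge_nodes` (indices of
#'   nodes incident to a planted bridge).
#' @export
make_block_precision <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    k <- spec$n_nodes_per_community
    p <- sum(k)
    communities <- rep(1:2, k)
    omega <- diag(p)
    pairs <- upper_pairs(p)
    within <- pairs[communities[pairs[, 1]] == communities[pairs[, 2]], ,
                    drop = FALSE]
    cross <- pairs[communities[pairs[, 1]] != communities[pairs[, 2]], ,
                   drop = FALSE]
    if (is.null(spec$edges)) {
      sel <- within[runif(nrow(within)) < spec$within_density, , drop = FALSE]
      nb <- min(spec$n_bridge_edges, nrow(cross))
      bsel <- cross[sample.int(nrow(cross), nb), , drop = FALSE]
      planted <- rbind(sel, bsel)
      weights <- runif(nrow(planted), spec$weight_range[1],
                       spec$weight_range[2])
      bridge_idx <- if (nb > 0) nrow(sel) + seq_len(nb) else integer()
    } else {
      planted <- as.matrix(spec$edges[, c("i", "j")])
      weights <- spec$edges$weight
      bridge_idx <- which(communities[planted[, 1]] !=
                            communities[planted[, 2]])
    }
    for (e in seq_len(nrow(planted))) {
      i <- planted[e, 1]; j <- planted[e, 2]
      omega[i, j] <- omega[j, i] <- -weights[e]
    }
    shrink <- 1
    for (iter in 1:200) {
      if (nrow(planted) == 0 || min(eigen(omega, symmetric = TRUE,
                                          only.values = TRUE)$values) > 0.01)
        break
      shrink <- shrink * 0.9
      off <- omega - diag(diag(omega))
      omega <- diag(diag(omega)) + off * 0.9
    }
    if (min(eigen(omega, symmetric = TRUE,
                  only.values = TRUE)$values) <= 0.01) {
      stop("could not reach positive definiteness by off-diagonal shrinkage",
           call. = FALSE)
    }
    edges <- if (nrow(planted) > 0) {
      data.frame(i = planted[, 1], j = planted[, 2],
                 weight = -omega[cbind(planted[, 1], planted[, 2])])
    } else {
      data.frame(i = integer(), j = integer(), weight = numeric())
    }
    bridge_edges <- edges[bridge_idx, , drop = FALSE]
    list(omega = omega, edges = edges, communities = communities,
         bridge_edges = bridge_edges,
         bridge_nodes = sort(unique(c(bridge_edges$i, bridge_edges$j))))
  })
}

#' Sample ordinal responses from a latent Gaussian graphical model
#'
#' Latent rows are drawn from the zero-mean Gaussian whose covariance is
#' the inverse of `precision` (rescaled to unit variances), then each node
#' is discretized by its threshold vector into categories `0 .. K-1`.
#'
#' @param precision symmetric positive definite precision matrix.
#' @param thresholds list of per-node strictly increasing cut points (or a
#'   single numeric vector recycled across nodes).
#' @param n number of respondents.
#' @param seed integer seed (deterministic given seed).
#' @return integer matrix of ordinal responses.
#' @export
sample_ordinal <- function(precision, thresholds, n, seed = NULL) {
  p <- nrow(precision)
  if (!is.list(thresholds)) thresholds <- rep(list(thresholds), p)
  stopifnot(length(thresholds) == p)
  sigma <- stats::cov2cor(solve(precision))
  R <- chol(sigma)
  with_seed(seed, {
    z <- matrix(rnorm(n * p), n, p) %*% R
    x <- matrix(0L, n, p)
    for (j in seq_len(p)) {
      x[, j] <- as.integer(findInterval(z[, j], thresholds[[j]]))
    }
    colnames(x) <- colnames(precision) %||% paste0("V", seq_len(p))
    x
  })
}

#' Simulate a complete synthetic survey with known truth
#'
#' Convenience wrapper: builds the block precision matrix from `spec`,
#' samples ordinal responses, and returns both along with the generating
#' truth (edges, communities, bridge nodes).
#'
#' @param spec a [generator_spec()].
#' @param labels node labels; default `F1..F7, P1..P13`-style per
#'   community.
#' @return list with `data` (ordinal matrix with a `communities`
#'   attribute) and `truth`.
#' @export
simulate_survey <- function(spec, labels = NULL) {
  truth <- make_block_precision(spec)
  p <- sum(spec$n_nodes_per_community)
  if (is.null(labels)) {
    labels <- c(paste0("F", seq_len(spec$n_nodes_per_community[1])),
                paste0("P", seq_len(spec$n_nodes_per_community[2])))
  }
  dimnames(truth$omega) <- list(labels, labels)
  seed2 <- if (is.null(spec$seed)) NULL else spec$seed + 1L
  data <- sample_ordinal(truth$omega, spec$thresholds, spec$n_respondents,
                         seed = seed2)
  colnames(data) <- labels
  attr(data, "communities") <- setNames(truth$communities, labels)
  list(data = data, truth = truth)
}

#' Gibbs-sample binary responses from an Ising model
#'
#' The conditional activation probability of node i given the others is
#' `plogis(tau_i + sum_j beta_ij x_j)` on 0/1 data. Rows are recorded from
#' a single Gibbs chain after `burn_in` full sweeps, one row every `thin`
#' sweeps.
#'
#' @param thresholds per-node intercepts `tau`.
#' @param couplings symmetric coupling matrix `beta` with zero diagonal.
#' @param n number of rows to record.
#' @param burn_in discarded initial sweeps.
#' @param thin sweeps between recorded rows.
#' @param seed integer seed.
#' @return binary integer matrix (`n` rows).
#' @export
sample_ising <- function(thresholds, couplings, n, burn_in = 1000,
                         thin = 10, seed = NULL) {
  couplings <- as.matrix(couplings)
  p <- length(thresholds)
  stopifnot(nrow(couplings) == p, ncol(couplings) == p)
  if (max(abs(couplings - t(couplings))) > 1e-8) {
    stop("couplings must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(couplings))) > 1e-8) {
    stop("couplings must have zero diagonal", call. = FALSE)
  }
  with_seed(seed, {
    x <- ising_gibbs_cpp(thresholds, couplings, as.integer(n),
                         as.integer(burn_in), as.integer(thin))
    colnames(x) <- colnames(couplings) %||% paste0("V", seq_len(p))
    x
  })
}
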