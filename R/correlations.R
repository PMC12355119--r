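#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum likelihood estimator: thresholds are fixed at the
#' inverse-normal transforms of the marginal cumulative proportions, then
#' the latent correlation maximizes the bivariate-normal contingency
#' likelihood over (-1, 1) (golden-section search, tolerance 1e-6, with
#' rectangle probabilities from a Gauss-Legendre bivariate normal CDF).
#'
#' @param x,y integer-coded ordinal vectors with at least 2 observed
#'   categories each.
#' @return list with `rho`, `x_thresholds`, `y_thresholds`.
#' @export
polychoric_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("undefined correlation: a variable is constant", call. = FALSE)
  }
  counts <- table(factor(x), factor(y))
  res <- polychoric_pair_cpp(unclass(counts), 1e-6)
  if (abs(res$rho) >= 0.999 - 1e-6) {
    warning("perfect association: rho clamped to +/-0.999")
    res$rho <- sign(res$rho) * 0.999
  }
  res
}

#' Correlation matrix for questionnaire data
#'
#' `method = "auto"` follows the ordinal-detection convention: polychoric
#' when every variable is integer-valued with at most 7 distinct levels,
#' Pearson otherwise. Pairwise polychoric matrices need not be positive
#' semi-definite; when required, the matrix is smoothed to the nearest PSD
#' matrix by clipping negative eigenvalues at zero and rescaling to a unit
#' diagonal.
#'
#' @param data respondent-by-variable matrix or data.frame (n >= 3).
#' @param method `"auto"`, `"polychoric"`, `"pearson"` or `"spearman"`.
#' @param smooth smooth to PSD when needed (default `TRUE`).
#' @return correlation matrix with attributes `method` (the method
#'   actually used) and `smoothed`.
#' @export
correlation_matrix <- function(data,
                               method = c("auto", "polychoric", "pearson",
                                          "spearman"),
                               smooth = TRUE) {
  method <- match.arg(method)
  data <- as_response_matrix(data)
  if (nrow(data) < 3) stop("need at least 3 respondents", call. = FALSE)
  labels <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
  colnames(data) <- labels
  const <- which(apply(data, 2, function(v) length(unique(v)) < 2))
  if (length(const) > 0) {
    stop(sprintf("constant column(s): %s",
                 paste(labels[const], collapse = ", ")), call. = FALSE)
  }
  method <- resolve_cor_method(data, method)
  R <- switch(method,
    polychoric = {
      storage.mode(data) <- "integer"
      polychoric_matrix_cpp(data, 1e-6)$rho
    },
    pearson = cor(data),
    spearman = cor(data, method = "spearman"))
  dimnames(R) <- list(labels, labels)
  smoothed <- FALSE
  # Pearson/Spearman sample correlations are Gram matrices and hence PSD;
  # only pairwise polychoric estimates can need smoothing.
  if (smooth && method == "polychoric") {
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      lam <- pmax(ev$values, 1e-8)
      R <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
      d <- sqrt(diag(R))
      R <- R / tcrossprod(d)
      diag(R) <- 1
      R <- (R + t(R)) / 2
      dimnames(R) <- list(labels, labels)
      smoothed <- TRUE
    }
  }
  attr(R, "method") <- method
  attr(R, "smoothed") <- smoothed
  R
}

# Resolve the "auto" dispatch rule: polychoric when every variable is
# integer-valued with at most 7 distinct levels, Pearson otherwise.
resolve_cor_method <- function(data, method) {
  if (method != "auto") return(method)
  ordinal <- all(data == round(data)) &&
    all(apply(data, 2, function(v) length(unique(v))) <= 7)
  if (ordinal) "polychoric" else "pearson"
}

# Dependent overlapping correlation test (Hittner et al. back-transformed
# average z): compares cor(a,c) and cor(b,c), which share variable c, with
# cor(a,b) known. Returns the two-sided p-value.
hittner_test <- function(r_ac, r_bc, r_ab, n) {
  z1 <- atanh(r_ac)
  z2 <- atanh(r_bc)
  rbar <- tanh((z1 + z2) / 2)
  cov_term <- (r_ab * (1 - 2 * rbar^2) -
                 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ab^2)) / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term))
  2 * pnorm(-abs(z))
}

#' Screen redundant node pairs by topological overlap
#'
#' For every candidate pair `(a, b)` with `|cor(a, b)| >= min_correlation`,
#' each third node `c` contributes a dependent-correlation test of whether
#' `cor(a, c)` and `cor(b, c)` differ (Hittner back-transformed average z).
#' The pair is flagged redundant when the proportion of third nodes with a
#' significantly different correlation falls below
#' `proportion_threshold` - i.e. the two nodes relate to the rest of the
#' network near-identically.
#'
#' @param data respondent-by-node matrix (>= 4 nodes).
#' @param p_threshold significance level for each third-node test.
#' @param proportion_threshold flag a pair when the proportion of
#'   significantly different third-node correlations is below this.
#' @param min_correlation only pairs at least this strongly correlated are
#'   candidates.
#' @param method correlation method passed to [correlation_matrix()].
#' @return list with `redundant` (data.frame `node_a`, `node_b`,
#'   `correlation`, `prop_significant`), `suggested_reductions` (for each
#'   flagged pair, the member with the weaker remaining connectivity), and
#'   the thresholds used.
#' @export
goldbricker <- function(data, p_threshold = 0.05,
                        proportion_threshold = 0.25,
                        min_correlation = 0.50,
                        method = "auto") {
  data <- as_response_matrix(data)
  p <- ncol(data)
  if (p < 4) stop("need at least 4 nodes", call. = FALSE)
  n <- nrow(data)
  R <- correlation_matrix(data, method = method)
  labels <- colnames(R)
  pairs <- upper_pairs(p)
  rows <- list()
  drop_suggest <- character()
  for (e in seq_len(nrow(pairs))) {
    a <- pairs[e, 1]; b <- pairs[e, 2]
    if (abs(R[a, b]) < min_correlation) next
    others <- setdiff(seq_len(p), c(a, b))
    if (length(others) < 3) stop("fewer than 3 third nodes", call. = FALSE)
    pv <- vapply(others, function(cc) {
      hittner_test(R[a, cc], R[b, cc], R[a, b], n)
    }, numeric(1))
    prop_sig <- mean(pv < p_threshold)
    if (prop_sig < proportion_threshold) {
      rows[[length(rows) + 1]] <- data.frame(
        node_a = labels[a], node_b = labels[b],
        correlation = R[a, b], prop_significant = prop_sig)
      conn_a <- sum(abs(R[a, others]))
      conn_b <- sum(abs(R[b, others]))
      drop_suggest <- c(drop_suggest,
                        if (conn_a < conn_b) labels[a] else labels[b])
    }
  }
  redundant <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(node_a = character(), node_b = character(),
               correlation = numeric(), prop_significant = numeric())
  }
  list(redundant = redundant,
       suggested_reductions = unique(drop_suggest),
       settings = list(p_threshold = p_threshold,
                       proportion_threshold = proportion_threshold,
                       min_correlation = min_correlation))
}
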