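#' Dichotomize ordinal responses
#'
#' Any response above 0 becomes 1 (symptom present), 0 stays 0. Columns
#' that become constant are reported in the `constant_columns` attribute;
#' they cannot enter an Ising fit.
#'
#' @param data ordinal respondent-by-item matrix.
#' @return binary integer matrix with a `constant_columns` attribute.
#' @export
dichotomize <- function(data) {
  data <- as_response_matrix(data)
  x <- (data > 0) + 0L
  dimnames(x) <- dimnames(data)
  const <- colnames(x)[apply(x, 2, function(v) length(unique(v)) < 2)]
  attr(x, "constant_columns") <- const
  x
}

# EBIC-selected L1 logistic regression of y on x (binary predictors).
# Returns intercept and coefficient vector. With fewer than two
# predictors glmnet cannot be used; an unpenalized fit is compared with
# the null model by EBIC instead.
elasso_node <- function(y, x, gamma) {
  n <- length(y)
  pk <- ncol(x)
  if (pk >= 2) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1)
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    k <- fit$df
    ebic <- dev + k * log(n) + 2 * gamma * k * log(pk)
    best <- which.min(ebic)
    cf <- as.numeric(stats::coef(fit, s = fit$lambda[best]))
    list(intercept = cf[1], beta = cf[-1])
  } else {
    d <- data.frame(y = y, x1 = x[, 1])
    full <- stats::glm(y ~ x1, family = stats::binomial(), data = d)
    null <- stats::glm(y ~ 1, family = stats::binomial(), data = d)
    ebic_full <- full$deviance + 1 * log(n)
    ebic_null <- null$deviance
    if (ebic_full < ebic_null) {
      cf <- stats::coef(full)
      list(intercept = cf[1], beta = cf[2])
    } else {
      list(intercept = stats::coef(null)[1], beta = 0)
    }
  }
}

#' Fit an Ising model by nodewise penalized logistic regression (eLasso)
#'
#' Each node is regressed on all others with an L1-penalized logistic
#' regression; the penalty is selected per node by
#' `EBIC = deviance + k log n + 2 gamma k log(p - 1)`. The two directed
#' estimates of each coupling are combined by `rule`: `"AND"` keeps an
#' edge only when both are nonzero (averaging them), `"OR"` when either
#' is (averaging the nonzero ones). Thresholds are the selected
#' intercepts.
#'
#' @param data binary respondent-by-node matrix (see [dichotomize()]).
#' @param gamma EBIC hyperparameter (default 0.25, the conservative
#'   eLasso convention).
#' @param rule `"AND"` (default) or `"OR"`.
#' @param cap absolute bound on coefficients; estimates beyond it signal
#'   separation and are capped with a warning.
#' @return object of class `ising_model`: `thresholds`, `couplings`,
#'   `rule`, `gamma`, `labels`.
#' @export
fit_ising <- function(data, gamma = 0.25, rule = c("AND", "OR"), cap = 15) {
  rule <- match.arg(rule)
  data <- as_response_matrix(data)
  if (!all(data %in% c(0, 1))) {
    stop("fit_ising expects 0/1 data; see dichotomize()", call. = FALSE)
  }
  labels <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
  colnames(data) <- labels
  p <- ncol(data)
  if (p < 2) stop("need at least 2 nodes", call. = FALSE)
  const <- labels[apply(data, 2, function(v) length(unique(v)) < 2)]
  if (length(const) > 0) {
    stop(sprintf("constant column(s): %s", paste(const, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(data) < 50) warning("n < 50: Ising estimates will be unstable")
  directed <- matrix(0, p, p, dimnames = list(labels, labels))
  tau <- numeric(p)
  for (j in seq_len(p)) {
    fit <- elasso_node(data[, j], data[, -j, drop = FALSE], gamma)
    tau[j] <- fit$intercept
    directed[j, -j] <- fit$beta
  }
  if (max(abs(directed), abs(tau)) > cap) {
    warning("separation suspected: coefficients capped at +/-", cap)
    directed <- pmin(pmax(directed, -cap), cap)
    tau <- pmin(pmax(tau, -cap), cap)
  }
  both <- directed != 0 & t(directed) != 0
  either <- directed != 0 | t(directed) != 0
  avg <- (directed + t(directed)) / 2
  couplings <- switch(rule,
    AND = ifelse(both, avg, 0),
    OR = ifelse(both, avg, ifelse(either, directed + t(directed), 0)))
  diag(couplings) <- 0
  structure(list(thresholds = setNames(tau, labels),
                 couplings = couplings, rule = rule, gamma = gamma,
                 labels = labels),
            class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  ne <- sum(x$couplings[upper.tri(x$couplings)] != 0)
  cat(sprintf("<ising_model> %d nodes, %d couplings (%s rule, gamma = %g)\n",
              length(x$labels), ne, x$rule, x$gamma))
  invisible(x)
}

#' Nodewise predictability of an Ising model
#'
#' Classification-based predictability: each node is predicted from the
#' others through the fitted conditional
#' (`tau_i + sum_j beta_ij x_j > 0`), and the accuracy is normalized
#' against the marginal majority class:
#' `(accuracy - majority) / (1 - majority)`, floored at 0. A disconnected
#' node scores ~0; a deterministic copy of its neighbors scores ~1.
#'
#' @param model an [fit_ising()] model.
#' @param data binary matrix the model is evaluated on.
#' @return named vector in `[0, 1]`.
#' @export
nodewise_predictability <- function(model, data) {
  stopifnot(inherits(model, "ising_model"))
  data <- as_response_matrix(data)
  data <- data[, model$labels, drop = FALSE]
  vapply(seq_along(model$labels), function(j) {
    eta <- model$thresholds[j] +
      data[, -j, drop = FALSE] %*% model$couplings[j, -j]
    pred <- as.integer(eta > 0)
    acc <- mean(pred == data[, j])
    maj <- max(mean(data[, j]), 1 - mean(data[, j]))
    if (maj >= 1) return(0)
    max(0, (acc - maj) / (1 - maj))
  }, numeric(1)) |> setNames(model$labels)
}

#' Simulate a threshold-perturbation intervention on one node
#'
#' The perturbation unit is the standard deviation of the fitted
#' threshold vector; amplification raises the node's threshold by
#' `sd_multiplier` units (raising its activation probability),
#' attenuation lowers it. Baseline and perturbed models are
#' Gibbs-sampled with a shared seed stream (common random numbers), and
#' the intervention effect is the change in the mean total symptom sum
#' score, along with per-node prevalence changes.
#'
#' @param model an [fit_ising()] model.
#' @param node node label or index.
#' @param direction `"attenuate"` or `"amplify"`.
#' @param sd_multiplier perturbation size in threshold-SD units
#'   (default 2).
#' @param n_sim simulated responses per condition (default 10000).
#' @param burn_in,thin Gibbs settings.
#' @param seed integer seed.
#' @return one-row data.frame: `node`, `direction`, `delta_sum_score`,
#'   `baseline_sum_score`, plus a `delta_prevalence` attribute (named
#'   per-node vector).
#' @export
simulate_intervention <- function(model, node,
                                  direction = c("attenuate", "amplify"),
                                  sd_multiplier = 2, n_sim = 10000,
                                  burn_in = 1000, thin = 1, seed = NULL) {
  stopifnot(inherits(model, "ising_model"))
  direction <- match.arg(direction)
  if (is.character(node)) node <- match(node, model$labels)
  stopifnot(!is.na(node), node >= 1, node <= length(model$labels))
  sd_tau <- sd(model$thresholds)
  shift <- sd_multiplier * sd_tau * if (direction == "amplify") 1 else -1
  tau2 <- model$thresholds
  tau2[node] <- tau2[node] + shift
  base <- sample_ising(model$thresholds, model$couplings, n_sim,
                       burn_in = burn_in, thin = thin, seed = seed)
  pert <- sample_ising(tau2, model$couplings, n_sim,
                       burn_in = burn_in, thin = thin, seed = seed)
  out <- data.frame(node = model$labels[node], direction = direction,
                    delta_sum_score = mean(rowSums(pert)) -
                      mean(rowSums(base)),
                    baseline_sum_score = mean(rowSums(base)))
  attr(out, "delta_prevalence") <-
    setNames(colMeans(pert) - colMeans(base), model$labels)
  out
}

#' Simulate interventions on every node in both directions
#'
#' @param model an [fit_ising()] model.
#' @param sd_multiplier,n_sim,burn_in,thin,seed see
#'   [simulate_intervention()]; each node/direction run derives its seed
#'   from `seed` deterministically.
#' @return object of class `intervention_result`: data.frame with one
#'   row per node x direction and a `delta_prevalence` matrix attribute.
#' @export
simulate_all_interventions <- function(model, sd_multiplier = 2,
                                       n_sim = 10000, burn_in = 1000,
                                       thin = 1, seed = NULL) {
  stopifnot(inherits(model, "ising_model"))
  grid <- expand.grid(node = seq_along(model$labels),
                      direction = c("attenuate", "amplify"),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  prev <- matrix(NA_real_, nrow(grid), length(model$labels),
                 dimnames = list(NULL, model$labels))
  for (r in seq_len(nrow(grid))) {
    seed_r <- if (is.null(seed)) NULL else seed + r
    res <- simulate_intervention(model, grid$node[r], grid$direction[r],
                                 sd_multiplier = sd_multiplier,
                                 n_sim = n_sim, burn_in = burn_in,
                                 thin = thin, seed = seed_r)
    prev[r, ] <- attr(res, "delta_prevalence")
    rows[[r]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "delta_prevalence") <- prev
  attr(out, "settings") <- list(sd_multiplier = sd_multiplier,
                                n_sim = n_sim, burn_in = burn_in,
                                thin = thin, seed = seed)
  class(out) <- c("intervention_result", class(out))
  out
}

#' Rank intervention targets from simulated interventions
#'
#' Aggravation candidates are ranked by descending sum-score change
#' under amplification; alleviation candidates by ascending (most
#' negative) change under attenuation. `relative_influence` expresses
#' each node's effect as a percentage of the total absolute effect in
#' its direction. Report thresholds flag candidates; they are
#' configurable reporting conventions, not model logic.
#'
#' @param results an [simulate_all_interventions()] result.
#' @param aggravation_threshold flag amplification effects at or above
#'   this sum-score change (default 0.01).
#' @param alleviation_threshold flag attenuation effects at or below
#'   minus this (default 1.0).
#' @return list with `aggravation` and `alleviation` data.frames
#'   (ranked, with `relative_influence` in percent and a `candidate`
#'   flag).
#' @export
rank_targets <- function(results, aggravation_threshold = 0.01,
                         alleviation_threshold = 1.0) {
  df <- as.data.frame(results)
  rank_one <- function(dir, decreasing, thr, sign) {
    d <- df[df$direction == dir, , drop = FALSE]
    d <- d[order(d$delta_sum_score, decreasing = decreasing), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    tot <- sum(abs(d$delta_sum_score))
    d$relative_influence <- if (tot > 0) {
      100 * d$delta_sum_score / tot
    } else 0
    d$candidate <- if (sign > 0) d$delta_sum_score >= thr else
      d$delta_sum_score <= -thr
    rownames(d) <- NULL
    d
  }
  list(aggravation = rank_one("amplify", TRUE, aggravation_threshold, 1),
       alleviation = rank_one("attenuate", FALSE, alleviation_threshold, -1))
}
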