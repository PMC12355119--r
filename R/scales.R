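#' Define a questionnaire scale
#'
#' A scale definition carries everything needed to score an instrument:
#' the ordered item labels, the admissible response range, which items are
#' reverse-scored, and how items group into subscales (dimensions).
#'
#' @param name scale name.
#' @param items character vector of item labels, in instrument order.
#' @param item_range integer length-2 vector, minimum and maximum response.
#' @param reverse character vector of reverse-scored item labels.
#' @param subscales named list mapping subscale name to a character vector
#'   of item labels; subscale item sets must be disjoint subsets of `items`.
#' @return an object of class `scale_definition`.
#' @export
scale_definition <- function(name, items, item_range = c(0L, 4L),
                             reverse = character(), subscales = list()) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop("duplicate item labels", call. = FALSE)
  item_range <- as.integer(item_range)
  if (length(item_range) != 2 || item_range[1] >= item_range[2]) {
    stop("item_range must be c(min, max) with min < max", call. = FALSE)
  }
  reverse <- as.character(reverse)
  if (!all(reverse %in% items)) {
    stop("reverse items must be declared item labels", call. = FALSE)
  }
  sub_items <- unlist(subscales, use.names = FALSE)
  if (!all(sub_items %in% items)) {
    stop("subscale items must be declared item labels", call. = FALSE)
  }
  if (anyDuplicated(sub_items)) {
    stop("subscales must not overlap", call. = FALSE)
  }
  structure(list(name = name, items = items, item_range = item_range,
                 reverse = reverse, subscales = subscales),
            class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items in [%d, %d], %d reverse, %d subscales\n",
              x$name, length(x$items), x$item_range[1], x$item_range[2],
              length(x$reverse), length(x$subscales)))
  invisible(x)
}

#' Read a scale definition from a YAML config file
#'
#' The file must contain fields `name`, `items`, `range`, and optionally
#' `reverse` and `subscales` (a map of subscale name to item list).
#'
#' @param path path to a YAML file.
#' @return a [scale_definition()].
#' @export
read_scale_definition <- function(path) {
  cfg <- yaml::read_yaml(path)
  scale_definition(name = cfg$name,
                   items = cfg$items,
                   item_range = cfg$range,
                   reverse = cfg$reverse %||% character(),
                   subscales = cfg$subscales %||% list())
}

#' Packaged Fear of Cancer Recurrence Inventory definition
#'
#' 42 items on a 0-4 Likert scale across 7 dimensions (triggers, severity,
#' psychological distress, functioning impairments, insight, reassurance,
#' coping strategies), with item 13 reverse-scored. The item-to-dimension
#' layout ships as an editable YAML default in `inst/extdata/fcri.yaml`.
#'
#' @return a [scale_definition()].
#' @export
fcri_definition <- function() {
  read_scale_definition(system.file("extdata", "fcri.yaml",
                                    package = "symptomnet"))
}

#' Packaged Pain Catastrophizing Scale definition
#'
#' 13 items on a 0-4 Likert scale (total score 0-52) across rumination,
#' magnification and helplessness subscales (`inst/extdata/pcs.yaml`).
#'
#' @return a [scale_definition()].
#' @export
pcs_definition <- function() {
  read_scale_definition(system.file("extdata", "pcs.yaml",
                                    package = "symptomnet"))
}

#' Score an instrument
#'
#' Reverse items are transformed as `v' = max + min - v` before summation;
#' subscale scores and the total are sums of the (transformed) item scores.
#'
#' @param def a [scale_definition()].
#' @param data respondent-by-item matrix or data.frame whose columns cover
#'   the definition's items; no missing values (see [handle_missing()]).
#' @return a data.frame with one row per respondent: subscale scores and
#'   `total`.
#' @export
score_scale <- function(def, data) {
  stopifnot(inherits(def, "scale_definition"))
  data <- as_response_matrix(data)
  missing_items <- setdiff(def$items, colnames(data))
  if (length(missing_items) > 0) {
    stop(sprintf("unknown item id(s): data lacks %s",
                 paste(missing_items, collapse = ", ")), call. = FALSE)
  }
  data <- data[, def$items, drop = FALSE]
  check_ordinal_range(data, def$item_range)
  rng <- def$item_range
  for (it in def$reverse) {
    data[, it] <- rng[2] + rng[1] - data[, it]
  }
  out <- data.frame(row.names = rownames(data) %||% seq_len(nrow(data)))
  for (s in names(def$subscales)) {
    out[[s]] <- rowSums(data[, def$subscales[[s]], drop = FALSE])
  }
  out$total <- rowSums(data)
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))` computed on
#' the raw (unstandardized) item covariances.
#'
#' @param data respondent-by-item matrix or data.frame.
#' @param items item labels to use (default: all columns).
#' @return scalar in (-Inf, 1].
#' @export
cronbach_alpha <- function(data, items = colnames(data)) {
  data <- as_response_matrix(data)
  if (!is.null(items)) data <- data[, items, drop = FALSE]
  k <- ncol(data)
  if (k < 2) stop("need at least 2 items", call. = FALSE)
  if (nrow(data) < 3) stop("need at least 3 respondents", call. = FALSE)
  total_var <- var(rowSums(data))
  if (total_var <= 0) {
    stop("undefined alpha: total score variance is zero", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(data, 2, var)) / total_var)
}

#' Sample-size requirement for a partial-correlation network
#'
#' The number of free parameters of a p-node Gaussian graphical model is
#' p threshold parameters plus p(p-1)/2 pairwise parameters; the sample
#' should at least exceed that count. An anticipated attrition rate
#' inflates the recruitment target: `required_n = ceiling(minimum_n /
#' (1 - attrition))`.
#'
#' @param n_nodes number of network nodes (>= 2).
#' @param attrition anticipated attrition proportion in `[0, 1)`.
#' @return list with `threshold_params`, `pairwise_params`, `minimum_n`,
#'   `required_n`.
#' @export
network_sample_size <- function(n_nodes, attrition = 0) {
  if (n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  if (attrition < 0 || attrition >= 1) {
    stop("attrition must be in [0, 1)", call. = FALSE)
  }
  tp <- as.integer(n_nodes)
  pp <- as.integer(n_nodes * (n_nodes - 1) / 2)
  minimum_n <- tp + pp
  list(threshold_params = tp, pairwise_params = pp, minimum_n = minimum_n,
       required_n = as.integer(ceiling(minimum_n / (1 - attrition))))
}

#' Handle missing questionnaire responses
#'
#' The default (and only) policy is listwise deletion: any respondent with
#' at least one missing item is dropped, matching the practice of treating
#' incomplete questionnaires as invalid. Imputation is deliberately not
#' offered.
#'
#' @param data respondent-by-item matrix or data.frame (may contain `NA`).
#' @param policy currently only `"listwise"`.
#' @return list with `data` (retained respondents) and `report`
#'   (`n_enrolled`, `n_dropped`, `n_retained`, `pct_dropped`,
#'   `pct_retained`; percentages rounded half-up to 1 decimal).
#' @export
handle_missing <- function(data, policy = c("listwise")) {
  policy <- match.arg(policy)
  data <- as_response_matrix(data, allow_missing = TRUE)
  n <- nrow(data)
  keep <- stats::complete.cases(data)
  if (!any(keep)) stop("all respondents dropped by missing-data policy",
                       call. = FALSE)
  dropped <- sum(!keep)
  list(data = data[keep, , drop = FALSE],
       report = list(n_enrolled = n,
                     n_dropped = dropped,
                     n_retained = n - dropped,
                     pct_dropped = round_half_up(dropped / n * 100, 1),
                     pct_retained = round_half_up((n - dropped) / n * 100, 1),
                     policy = policy))
}

#' Build the analysis node matrix from item-level responses
#'
#' The network nodes are the 7 FCRI dimension scores (F1..F7) and the 13
#' single PCS items (P1..P13). Dimension scores enter as raw sums by
#' default; `standardize = TRUE` z-scores every node column.
#'
#' @param data respondent-by-item matrix/data.frame containing all FCRI
#'   and PCS item columns.
#' @param fcri,pcs the two scale definitions.
#' @param fcri_labels,pcs_labels node labels, matched by position to the
#'   FCRI subscale order and the PCS item order.
#' @param standardize z-score the node columns.
#' @return numeric matrix with one column per node and a `communities`
#'   attribute (named vector: 1 = FCR, 2 = PC).
#' @export
build_node_matrix <- function(data, fcri = fcri_definition(),
                              pcs = pcs_definition(),
                              fcri_labels = paste0("F", seq_along(fcri$subscales)),
                              pcs_labels = paste0("P", seq_along(pcs$items)),
                              standardize = FALSE) {
  fs <- score_scale(fcri, data)
  fdim <- as.matrix(fs[, names(fcri$subscales), drop = FALSE])
  colnames(fdim) <- fcri_labels
  pit <- as_response_matrix(data)[, pcs$items, drop = FALSE]
  colnames(pit) <- pcs_labels
  nodes <- cbind(fdim, pit)
  if (standardize) nodes <- scale(nodes)
  communities <- setNames(c(rep(1L, ncol(fdim)), rep(2L, ncol(pit))),
                          colnames(nodes))
  attr(nodes, "communities") <- communities
  nodes
}
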