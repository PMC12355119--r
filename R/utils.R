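#' Round half away from zero
#'
#' Base R rounds half to even; survey reporting conventions round half up
#' (e.g. a 4.65% drop rate is reported as 4.7%).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. A NULL seed uses (and
# advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Coerce questionnaire input (matrix or data.frame) to an integer-checked
# numeric matrix, keeping respondent ids from row names when present.
as_response_matrix <- function(data, allow_missing = FALSE) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("response data must be a numeric matrix or data.frame", call. = FALSE)
  }
  if (!allow_missing && anyNA(data)) {
    stop("response data contains missing values; run handle_missing() first",
         call. = FALSE)
  }
  data
}

check_ordinal_range <- function(data, item_range) {
  vals <- data[!is.na(data)]
  if (any(vals != round(vals))) {
    stop("ordinal responses must be integers", call. = FALSE)
  }
  if (any(vals < item_range[1] | vals > item_range[2])) {
    stop(sprintf("responses outside declared range [%d, %d]",
                 item_range[1], item_range[2]), call. = FALSE)
  }
  invisible(TRUE)
}

upper_pairs <- function(p) {
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
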