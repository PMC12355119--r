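# Score-based Bayesian network structure learning over (approximately)
# Gaussian node scores: greedy hill climbing on the decomposable
# linear-Gaussian BIC, bootstrap model averaging with a direction-
# consistency rule, and complexity metrics.

# Sufficient statistics: centered cross-product matrix and n.
bn_stats <- function(data) {
  data <- as_response_matrix(data)
  x <- scale(data, center = TRUE, scale = FALSE)
  list(S = crossprod(x), n = nrow(data),
       labels = colnames(data) %||% paste0("V", seq_len(ncol(data))))
}

# Local linear-Gaussian BIC of node j given an integer parent set:
# loglik - (|parents| + 2)/2 * log n (coefficients + intercept + noise
# variance). Higher is better.
bn_local_score <- function(j, parents, stats, cache = NULL) {
  key <- paste0(j, "|", paste(sort(parents), collapse = ","))
  if (!is.null(cache) && !is.null(val <- cache[[key]])) return(val)
  S <- stats$S; n <- stats$n
  if (length(parents) == 0) {
    rss <- S[j, j]
  } else {
    Spp <- S[parents, parents, drop = FALSE]
    Spj <- S[parents, j]
    sol <- tryCatch(solve(Spp, Spj), error = function(e) {
      warning("singular local regression; ridge fallback")
      solve(Spp + diag(1e-8 * mean(diag(Spp)), length(parents)), Spj)
    })
    rss <- S[j, j] - sum(Spj * sol)
  }
  sigma2 <- max(rss / n, 1e-12)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  val <- ll - 0.5 * (length(parents) + 2) * log(n)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

# Is there a directed path from `from` to `to`?
bn_has_path <- function(amat, from, to) {
  p <- nrow(amat)
  seen <- logical(p)
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- which(colSums(amat[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Total network score of a DAG
#'
#' The decomposable Gaussian BIC: the sum over nodes of the local
#' linear-Gaussian log-likelihood minus `(parents + 2)/2 * log(n)`.
#' Higher is better (typically negative).
#'
#' @param data numeric respondent-by-node matrix.
#' @param amat logical adjacency matrix (`amat[i, j]` means `i -> j`).
#' @return scalar score.
#' @export
dag_score <- function(data, amat) {
  stats <- bn_stats(data)
  sum(vapply(seq_len(ncol(amat)), function(j) {
    bn_local_score(j, which(amat[, j]), stats)
  }, numeric(1)))
}

# One greedy pass from a starting DAG to a local score maximum.
bn_greedy <- function(amat, stats, cache, max_iter = 500) {
  p <- nrow(amat)
  locals <- vapply(seq_len(p), function(j) {
    bn_local_score(j, which(amat[, j]), stats, cache)
  }, numeric(1))
  # Moves are scanned in a fixed order and ties broken by first arrival:
  # a deterministic rule keeps score-equivalent orientations consistent
  # across bootstrap resamples (randomness enters via the restart
  # perturbations only).
  for (iter in seq_len(max_iter)) {
    best_delta <- 1e-10
    best_move <- NULL
    for (m in seq_len(p * p)) {
      i <- (m - 1) %/% p + 1
      j <- (m - 1) %% p + 1
      if (i == j) next
      if (!amat[i, j] && !amat[j, i]) { # add i -> j
        amat_try <- amat
        if (bn_has_path(amat, j, i)) next
        d <- bn_local_score(j, c(which(amat[, j]), i), stats, cache) -
          locals[j]
        if (d > best_delta) {
          best_delta <- d; best_move <- list(op = "add", i = i, j = j)
        }
      } else if (amat[i, j]) {
        pa_j <- which(amat[, j])
        d_del <- bn_local_score(j, setdiff(pa_j, i), stats, cache) -
          locals[j]
        if (d_del > best_delta) {
          best_delta <- d_del; best_move <- list(op = "delete", i = i, j = j)
        }
        # reverse i -> j: legal unless another i ~> j path exists
        amat2 <- amat; amat2[i, j] <- FALSE
        if (!bn_has_path(amat2, i, j)) {
          d_rev <- d_del +
            bn_local_score(i, c(which(amat[, i]), j), stats, cache) -
            locals[i]
          if (d_rev > best_delta) {
            best_delta <- d_rev
            best_move <- list(op = "reverse", i = i, j = j)
          }
        }
      }
    }
    if (is.null(best_move)) break
    i <- best_move$i; j <- best_move$j
    if (best_move$op == "add") {
      amat[i, j] <- TRUE
    } else if (best_move$op == "delete") {
      amat[i, j] <- FALSE
    } else {
      amat[i, j] <- FALSE
      amat[j, i] <- TRUE
      locals[i] <- bn_local_score(i, which(amat[, i]), stats, cache)
    }
    locals[j] <- bn_local_score(j, which(amat[, j]), stats, cache)
  }
  list(amat = amat, score = sum(locals))
}

#' Hill-climbing DAG search with random restarts
#'
#' Greedy add/delete/reverse search maximizing the decomposable Gaussian
#' BIC. Candidate moves are scanned in a fixed order (deterministic
#' tie-breaking, so score-equivalent orientations stay consistent across
#' bootstrap resamples). After the first climb, each restart
#' randomly perturbs the incumbent (a handful of random legal edge
#' changes) and climbs again; the highest-scoring acyclic graph is
#' returned.
#'
#' @param data numeric respondent-by-node matrix (n > node count).
#' @param restarts number of perturb-and-climb restarts (default 10).
#' @param perturb random edge changes per restart.
#' @param max_iter greedy steps per climb.
#' @param seed integer seed.
#' @return list of class `dag`: `amat` (logical adjacency, `[i, j]` is
#'   `i -> j`), `score`, `labels`.
#' @export
hill_climb <- function(data, restarts = 10, perturb = 5, max_iter = 500,
                       seed = NULL) {
  stats <- bn_stats(data)
  p <- length(stats$labels)
  if (stats$n <= p) stop("need more respondents than nodes", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  with_seed(seed, {
    amat <- matrix(FALSE, p, p)
    best <- bn_greedy(amat, stats, cache, max_iter)
    for (r in seq_len(max(restarts - 1, 0))) {
      amat <- best$amat
      for (s in seq_len(perturb)) {
        i <- sample.int(p, 1); j <- sample.int(p, 1)
        if (i == j) next
        if (amat[i, j]) {
          amat[i, j] <- FALSE
        } else if (!amat[j, i] && !bn_has_path(amat, j, i)) {
          amat[i, j] <- TRUE
        }
      }
      cand <- bn_greedy(amat, stats, cache, max_iter)
      if (cand$score > best$score) best <- cand
    }
    dimnames(best$amat) <- list(stats$labels, stats$labels)
    structure(list(amat = best$amat, score = best$score,
                   labels = stats$labels), class = "dag")
  })
}

#' Bootstrap-averaged Bayesian network
#'
#' `B` bootstrap resamples are each searched with [hill_climb()]. For
#' every unordered node pair the presence frequency (either direction)
#' and per-direction frequencies are recorded. The averaged network keeps
#' pairs whose presence frequency meets `presence_threshold` and whose
#' majority direction holds in at least `direction_threshold` of its
#' appearances (the direction-consistency retention rule); edges are
#' oriented by majority and inserted in decreasing presence order,
#' dropping any edge that would create a cycle (logged). Edge strength is
#' the change in the total network score when the edge is removed from
#' the averaged DAG refit on the full data: negative strength means the
#' edge improves fit (removing it lowers the score).
#'
#' @param data numeric respondent-by-node matrix.
#' @param B bootstrap resamples (>= 100).
#' @param presence_threshold minimum presence frequency (default 0.5).
#' @param direction_threshold minimum majority-direction frequency among
#'   appearances (default 0.75).
#' @param restarts hill-climb restarts per resample (default 2; the
#'   full-data search default of 10 is overkill inside a bootstrap).
#' @param seed integer seed.
#' @return object of class `dag_model`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `presence`, `direction`, `strength`), `amat`,
#'   `dropped` (edges removed to keep the graph acyclic), `mbs`, `bf`,
#'   `bic`, `parent_nodes`, `settings`.
#' @export
bootstrap_dag <- function(data, B = 200, presence_threshold = 0.5,
                          direction_threshold = 0.75, restarts = 2,
                          seed = NULL) {
  data <- as_response_matrix(data)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  n <- nrow(data)
  labels <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
  colnames(data) <- labels
  p <- length(labels)
  dircount <- matrix(0, p, p, dimnames = list(labels, labels))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- hill_climb(data[idx, , drop = FALSE], restarts = restarts,
                        seed = NULL)
      dircount <- dircount + fit$amat
    }
  })
  pairs <- upper_pairs(p)
  presence <- (dircount[pairs] + t(dircount)[pairs]) / B
  fwd <- dircount[pairs]
  bwd <- t(dircount)[pairs]
  appearances <- fwd + bwd
  dirfreq <- ifelse(appearances > 0, pmax(fwd, bwd) / appearances, 0)
  keep <- presence >= presence_threshold & dirfreq >= direction_threshold
  kept <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                     presence = presence[keep], direction = dirfreq[keep],
                     forward = fwd[keep] >= bwd[keep])
  kept <- kept[order(-kept$presence), , drop = FALSE]
  amat <- matrix(FALSE, p, p, dimnames = list(labels, labels))
  dropped <- list()
  rows <- list()
  for (r in seq_len(nrow(kept))) {
    from <- if (kept$forward[r]) kept$i[r] else kept$j[r]
    to <- if (kept$forward[r]) kept$j[r] else kept$i[r]
    if (bn_has_path(amat, to, from)) {
      dropped[[length(dropped) + 1]] <-
        data.frame(from = labels[from], to = labels[to],
                   presence = kept$presence[r])
      next
    }
    amat[from, to] <- TRUE
    rows[[length(rows) + 1]] <-
      data.frame(from = labels[from], to = labels[to],
                 presence = kept$presence[r],
                 direction = kept$direction[r])
  }
  edges <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(from = character(), to = character(),
               presence = numeric(), direction = numeric())
  # score-based strength on the full data
  stats <- bn_stats(data)
  edges$strength <- vapply(seq_len(nrow(edges)), function(r) {
    j <- match(edges$to[r], labels)
    i <- match(edges$from[r], labels)
    pa <- which(amat[, j])
    bn_local_score(j, setdiff(pa, i), stats) - bn_local_score(j, pa, stats)
  }, numeric(1))
  metrics <- dag_metrics(amat, data)
  structure(list(nodes = labels, edges = edges, amat = amat,
                 dropped = if (length(dropped) > 0) do.call(rbind, dropped)
                           else NULL,
                 mbs = metrics$mbs, bf = metrics$bf, bic = metrics$bic,
                 parent_nodes = metrics$parent_nodes,
                 settings = list(B = B,
                                 presence_threshold = presence_threshold,
                                 direction_threshold = direction_threshold,
                                 restarts = restarts, seed = seed)),
            class = "dag_model")
}

#' @export
print.dag_model <- function(x, ...) {
  cat(sprintf("<dag_model> %d nodes, %d directed edges (MBS = %.2f, BF = %.2f",
              length(x$nodes), nrow(x$edges), x$mbs, x$bf))
  if (!is.na(x$bic)) cat(sprintf(", BIC = %.2f", x$bic))
  cat(")\n")
  if (length(x$parent_nodes) > 0) {
    cat("  parent nodes:", paste(x$parent_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' DAG complexity metrics
#'
#' The Markov blanket of a node is its parents, children and co-parents
#' (other parents of its children); `mbs` is the mean blanket size and
#' `bf` (branching factor) the mean number of children per node. Parent
#' nodes are roots that drive the network: out-degree > 0, in-degree 0.
#'
#' @param dag a `dag_model`, `dag`, or logical adjacency matrix
#'   (`[i, j]` = `i -> j`).
#' @param data optional data to compute the full-network BIC score.
#' @return list with `mbs`, `bf`, `bic`, `parent_nodes`, and the
#'   per-node `blanket_size`.
#' @export
dag_metrics <- function(dag, data = NULL) {
  amat <- if (is.matrix(dag)) dag else dag$amat
  p <- nrow(amat)
  labels <- rownames(amat) %||% paste0("V", seq_len(p))
  blanket <- vapply(seq_len(p), function(v) {
    parents <- which(amat[, v])
    children <- which(amat[v, ])
    coparents <- unlist(lapply(children, function(ch) which(amat[, ch])))
    length(setdiff(unique(c(parents, children, coparents)), v))
  }, numeric(1))
  outdeg <- rowSums(amat)
  indeg <- colSums(amat)
  list(mbs = mean(blanket),
       bf = mean(outdeg),
       bic = if (is.null(data)) NA_real_ else dag_score(data, amat),
       parent_nodes = labels[outdeg > 0 & indeg == 0],
       blanket_size = setNames(blanket, labels))
}
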