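#' Node strength
#'
#' `Str_i = sum_j |w_ij|`: the sum of absolute edge weights at a node.
#'
#' @param net a [network_model()].
#' @return named numeric vector.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "network_model"))
  setNames(rowSums(abs(net$weights)), net$labels)
}

#' One-step expected influence
#'
#' `EI_i = sum_j w_ij`: the signed sum of a node's edge weights. Equal to
#' strength on all-positive networks.
#'
#' @param net a [network_model()].
#' @return named numeric vector.
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "network_model"))
  setNames(rowSums(net$weights), net$labels)
}

#' Betweenness and closeness centrality
#'
#' Shortest paths use edge lengths `1/|w_ij|` so strong edges are short.
#' Betweenness counts unordered pairs (endpoints excluded) with
#' fractional credit for tied shortest paths. Closeness is the
#' unnormalized inverse total distance `1/sum_j d_ij`; on disconnected
#' graphs it is computed within the node's component (unreachable pairs
#' excluded) and the result carries a `disconnected` attribute. Isolated
#' nodes get betweenness 0 and closeness `NA`.
#'
#' @param net a [network_model()].
#' @return data.frame with columns `node`, `betweenness`, `closeness`.
#' @export
betweenness_closeness <- function(net) {
  stopifnot(inherits(net, "network_model"))
  g <- network_igraph(net)
  lens <- if (igraph::ecount(g) > 0) igraph::E(g)$length else numeric()
  bet <- igraph::betweenness(g, weights = lens, directed = FALSE)
  disconnected <- igraph::components(g)$no > 1
  clo <- suppressWarnings(
    igraph::closeness(g, weights = lens, normalized = FALSE))
  clo[!is.finite(clo)] <- NA_real_
  out <- data.frame(node = net$labels,
                    betweenness = as.numeric(bet),
                    closeness = as.numeric(clo))
  attr(out, "disconnected") <- disconnected
  out
}

#' Bridge centrality
#'
#' Bridge strength is the sum of absolute weights of a node's
#' cross-community edges; bridge expected influence (BEI) is the signed
#' analog. Identifies the symptoms that connect the two questionnaire
#' communities.
#'
#' @param net a [network_model()] with at least 2 communities assigned.
#' @return data.frame with `node`, `community`, `bridge_strength`,
#'   `bridge_expected_influence`.
#' @export
bridge_centrality <- function(net) {
  stopifnot(inherits(net, "network_model"))
  comm <- net$communities
  if (is.null(comm) || length(unique(comm)) < 2) {
    stop("bridge centrality requires >= 2 communities", call. = FALSE)
  }
  if (!is.null(names(comm))) comm <- comm[net$labels]
  cross <- outer(comm, comm, "!=")
  wc <- net$weights * cross
  data.frame(node = net$labels,
             community = as.integer(comm),
             bridge_strength = rowSums(abs(wc)),
             bridge_expected_influence = rowSums(wc))
}

#' Full centrality table
#'
#' Strength, expected influence, betweenness, closeness, and (when
#' communities are assigned) bridge strength and bridge expected
#' influence, per node. `standardized = TRUE` appends z-scored columns
#' (`*_z`) for plotting parity; raw values remain canonical.
#'
#' @param net a [network_model()].
#' @param standardized append z-scored columns.
#' @return data.frame, one row per node.
#' @export
centrality_table <- function(net, standardized = FALSE) {
  stopifnot(inherits(net, "network_model"))
  bc <- betweenness_closeness(net)
  out <- data.frame(node = net$labels,
                    strength = as.numeric(node_strength(net)),
                    expected_influence = as.numeric(expected_influence(net)),
                    betweenness = bc$betweenness,
                    closeness = bc$closeness)
  if (!is.null(net$communities) && length(unique(net$communities)) >= 2) {
    br <- bridge_centrality(net)
    out$community <- br$community
    out$bridge_strength <- br$bridge_strength
    out$bridge_expected_influence <- br$bridge_expected_influence
  }
  if (standardized) {
    num <- setdiff(names(out), c("node", "community"))
    for (v in num) {
      out[[paste0(v, "_z")]] <- as.numeric(scale(out[[v]]))
    }
  }
  attr(out, "disconnected") <- attr(bc, "disconnected")
  out
}
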