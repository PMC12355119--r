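# End-to-end orchestration: scoring -> redundancy screen -> separate and
# combined networks -> centrality/bridge -> stability -> group comparison
# -> Bayesian network -> Ising interventions, with one global seed fanned
# out to fixed per-stage offsets.

# stage seeds = global seed + these offsets
STAGE_SEED_OFFSETS <- c(stability_edges = 100L, stability_cs = 200L,
                        nct = 300L, bayesnet = 400L, ising = 500L)

#' Build a pipeline configuration
#'
#' All downstream defaults are overridable here; the configuration
#' round-trips losslessly through YAML ([read_run_config()] /
#' [write_run_config()]).
#'
#' @param seed global seed; stage seeds are derived as seed + fixed
#'   offsets (100 edge bootstrap, 200 case-dropping, 300 NCT, 400
#'   Bayesian network, 500 Ising).
#' @param input_level `"items"` (raw FCRI/PCS item columns, scored
#'   internally) or `"nodes"` (a ready node matrix).
#' @param group_col optional grouping column name (e.g. early vs.
#'   advanced stage) enabling the network comparison stage.
#' @param standardize z-score node columns before network estimation.
#' @param method,gamma,n_lambdas EBIC glasso settings.
#' @param goldbricker_args list of [goldbricker()] threshold overrides.
#' @param stages logical toggles; scoring and the combined network
#'   always run.
#' @param B_edges,B_cs,drop_grid,K_nct,B_dag,n_sim resampling sizes.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 7L, input_level = c("items", "nodes"),
                       group_col = NULL, standardize = FALSE,
                       method = "auto", gamma = 0.5, n_lambdas = 100,
                       goldbricker_args = list(),
                       stages = list(),
                       B_edges = 1000L, B_cs = 1000L,
                       drop_grid = seq(0.05, 0.75, by = 0.05),
                       K_nct = 1000L, B_dag = 200L, n_sim = 10000L) {
  input_level <- match.arg(input_level)
  default_stages <- list(goldbricker = TRUE, separate_networks = TRUE,
                         centrality = TRUE, stability = TRUE,
                         nct = !is.null(group_col), bayesnet = TRUE,
                         ising = TRUE)
  for (s in names(stages)) default_stages[[s]] <- isTRUE(stages[[s]])
  structure(list(seed = as.integer(seed), input_level = input_level,
                 group_col = group_col, standardize = standardize,
                 method = method, gamma = gamma,
                 n_lambdas = as.integer(n_lambdas),
                 goldbricker_args = goldbricker_args,
                 stages = default_stages,
                 B_edges = as.integer(B_edges), B_cs = as.integer(B_cs),
                 drop_grid = drop_grid, K_nct = as.integer(K_nct),
                 B_dag = as.integer(B_dag), n_sim = as.integer(n_sim)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full symptom-network analysis
#'
#' Stages execute in the analysis order: missing-data handling and
#' scoring (item-level input), redundancy screening, separate
#' community networks, the combined network with centrality and bridge
#' analysis, bootstrap stability, permutation group comparison (when a
#' grouping variable is supplied), Bayesian network averaging, and
#' Ising-model simulated interventions. Any stage failure aborts with a
#' stage-tagged error. Given the same config and seed, two runs produce
#' identical numeric output.
#'
#' @param data item-level data.frame (with FCRI/PCS item columns and
#'   optionally `group_col`) or a node-level matrix, per
#'   `config$input_level`.
#' @param config a [run_config()].
#' @param out_dir optional directory; stage artifacts (CSV/TSV/JSON) are
#'   written there.
#' @param group optional grouping vector (alternative to
#'   `config$group_col`).
#' @return list of class `run_report`.
#' @export
run_all <- function(data, config = run_config(), out_dir = NULL,
                    group = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(config = config, warnings = character(),
                 version = as.character(utils::packageVersion("symptomnet")))
  note <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              sprintf("[%s] %s", stage,
                                      conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  # -- scoring ---------------------------------------------------------
  if (config$input_level == "items") {
    df <- as.data.frame(data)
    if (!is.null(config$group_col) && config$group_col %in% names(df)) {
      group <- df[[config$group_col]]
      df[[config$group_col]] <- NULL
    }
    fcri <- fcri_definition(); pcs <- pcs_definition()
    items <- df[, c(fcri$items, pcs$items)]
    note("missing", {
      hm <- handle_missing(items)
      report$missing <- hm$report
      if (!is.null(group)) group <- group[stats::complete.cases(items)]
      items <- hm$data
    })
    note("scoring", {
      report$reliability <- c(
        fcri = cronbach_alpha(items, fcri$items),
        pcs = cronbach_alpha(items, pcs$items))
      nodes <- build_node_matrix(items, fcri, pcs,
                                 standardize = config$standardize)
    })
  } else {
    nodes <- as_response_matrix(data)
    if (is.null(attr(nodes, "communities"))) {
      stop("[stage scoring] node-level input needs a 'communities' attribute",
           call. = FALSE)
    }
    if (config$standardize) {
      comm <- attr(nodes, "communities")
      nodes <- scale(nodes)
      attr(nodes, "communities") <- comm
    }
  }
  communities <- attr(nodes, "communities")

  # -- redundancy ------------------------------------------------------
  if (isTRUE(config$stages$goldbricker)) {
    note("goldbricker", {
      report$goldbricker <- do.call(
        goldbricker, c(list(data = nodes, method = config$method),
                       config$goldbricker_args))
    })
  }

  # -- networks --------------------------------------------------------
  fitcfg <- function(x, comm) {
    fit_network(x, method = config$method, gamma = config$gamma,
                n_lambdas = config$n_lambdas, communities = comm)
  }
  if (isTRUE(config$stages$separate_networks)) {
    note("separate_networks", {
      for (cc in sort(unique(communities))) {
        sub <- nodes[, names(communities)[communities == cc], drop = FALSE]
        net <- fitcfg(sub, NULL)
        key <- paste0("network_community_", cc)
        report[[key]] <- net
        report[[paste0(key, "_summary")]] <- network_summary(net)
      }
    })
  }
  note("combined_network", {
    net <- fitcfg(nodes, communities)
    report$network <- net
    report$network_summary <- network_summary(net)
  })
  if (isTRUE(config$stages$centrality)) {
    note("centrality", {
      report$centrality <- centrality_table(report$network,
                                            standardized = TRUE)
    })
  }

  # -- stability -------------------------------------------------------
  if (isTRUE(config$stages$stability)) {
    note("stability", {
      report$edge_bootstrap <- edge_ci_bootstrap(
        nodes, B = config$B_edges,
        seed = config$seed + STAGE_SEED_OFFSETS[["stability_edges"]],
        method = config$method, gamma = config$gamma,
        n_lambdas = config$n_lambdas)
      idx <- c("strength",
               if (!is.null(communities)) "bridge_strength")
      report$cs <- cs_coefficient(
        nodes, indices = idx, drop_grid = config$drop_grid,
        B = config$B_cs,
        seed = config$seed + STAGE_SEED_OFFSETS[["stability_cs"]],
        method = config$method, gamma = config$gamma,
        n_lambdas = config$n_lambdas, communities = communities)
    })
  }

  # -- group comparison ------------------------------------------------
  if (isTRUE(config$stages$nct) && !is.null(group)) {
    note("nct", {
      lev <- unique(group)
      if (length(lev) != 2) stop("grouping must have exactly 2 levels")
      a <- nodes[group == lev[1], , drop = FALSE]
      b <- nodes[group == lev[2], , drop = FALSE]
      attr(a, "communities") <- attr(b, "communities") <- communities
      report$nct <- nct(a, b, K = config$K_nct,
                        seed = config$seed + STAGE_SEED_OFFSETS[["nct"]],
                        method = config$method, gamma = config$gamma,
                        n_lambdas = config$n_lambdas,
                        communities = communities)
    })
  }

  # -- Bayesian network ------------------------------------------------
  if (isTRUE(config$stages$bayesnet)) {
    note("bayesnet", {
      report$dag <- bootstrap_dag(
        nodes, B = config$B_dag,
        seed = config$seed + STAGE_SEED_OFFSETS[["bayesnet"]])
    })
  }

  # -- Ising interventions ---------------------------------------------
  if (isTRUE(config$stages$ising)) {
    note("ising", {
      # item/dimension scores are re-dichotomized at > 0
      bin <- dichotomize(nodes)
      model <- fit_ising(bin)
      report$ising <- model
      report$predictability <- nodewise_predictability(model, bin)
      sims <- simulate_all_interventions(
        model, n_sim = config$n_sim,
        seed = config$seed + STAGE_SEED_OFFSETS[["ising"]])
      report$interventions <- sims
      report$targets <- rank_targets(sims)
    })
  }

  if (!is.null(out_dir)) write_report_artifacts(report, out_dir)
  structure(report, class = "run_report")
}

# Write machine-readable per-stage artifacts.
write_report_artifacts <- function(report, out_dir) {
  js <- function(x, f) {
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  network_edge_list(report$network,
                    file = file.path(out_dir, "network_edges.tsv"))
  js(report$network_summary[names(report$network_summary) !=
                              "strongest_edges"], "network_summary.json")
  if (!is.null(report$centrality)) {
    write.csv(report$centrality, file.path(out_dir, "centrality.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$edge_bootstrap)) {
    write.csv(report$edge_bootstrap$edges,
              file.path(out_dir, "edge_bootstrap.csv"), row.names = FALSE)
  }
  if (!is.null(report$cs)) js(as.list(report$cs$cs), "cs.json")
  if (!is.null(report$nct)) {
    js(list(global_strength = as.list(report$nct$global_strength),
            S = report$nct$S, p_S = report$nct$p_S,
            M = report$nct$M, p_M = report$nct$p_M), "nct.json")
  }
  if (!is.null(report$dag)) {
    utils::write.table(report$dag$edges,
                       file.path(out_dir, "dag_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    js(list(mbs = report$dag$mbs, bf = report$dag$bf, bic = report$dag$bic,
            parent_nodes = report$dag$parent_nodes), "dag_metrics.json")
  }
  if (!is.null(report$interventions)) {
    write.csv(as.data.frame(report$interventions),
              file.path(out_dir, "interventions.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$missing)) {
    cat(sprintf("  respondents: %d retained of %d (%.1f%% dropped)\n",
                x$missing$n_retained, x$missing$n_enrolled,
                x$missing$pct_dropped))
  }
  s <- x$network_summary
  cat(sprintf("  combined network: %d nodes, %d/%d nonzero edges (%.2f%%)\n",
              s$n_nodes, s$n_nonzero, s$n_possible, s$pct_nonzero))
  if (!is.null(x$cs)) { cat("  CS: "); print(x$cs$cs) }
  if (!is.null(x$dag)) {
    cat(sprintf("  DAG: %d edges, MBS = %.2f, BF = %.2f\n",
                nrow(x$dag$edges), x$dag$mbs, x$dag$bf))
  }
  invisible(x)
}
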