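# Pipeline orchestration: optional coexpression preselection, causal
# pruning, gene selection, ensemble inference, and a run report.

#' Pipeline configuration
#'
#' Bundles the thresholds and per-stage settings of the full pipeline. The
#' causal thresholds default to 0.03 nats and the edge-weight cutoff to 0.5,
#' the operating point of the method on real data.
#'
#' @param cmi2_threshold Order-1 removal threshold (nats).
#' @param mi_threshold Order-0 removal threshold (nats); the order-0 score is
#'   mutual information, the zero-order case of the causal score, so it
#'   shares the default.
#' @param weight_threshold Absolute ensemble-weight cutoff for edges.
#' @param bins Bins per variable for the discrete joint-distribution
#'   estimates (default 3; see the methods vignette for the bias analysis
#'   behind this choice).
#' @param n_bootstraps Bootstraps per regression target.
#' @param rng_seed Master seed for all randomized stages.
#' @param estimator Causal-score estimator for the pruning stage:
#'   `"gaussian"` (default) or `"binned"`.
#' @param beta Soft threshold for the coexpression stage, or `NULL` to pick
#'   it by scale-free fit.
#' @param min_size,cut_height Module-detection settings.
#' @param gs_min,mm_min Hub-gene screening thresholds.
#' @param n_linear,n_product,lasso_grid Ensemble settings, see
#'   [ensemble_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cmi2_threshold = 0.03, mi_threshold = 0.03,
                            weight_threshold = 0.5, bins = 3L,
                            n_bootstraps = 500L, rng_seed = 1L,
                            estimator = c("gaussian", "binned"), beta = NULL,
                            min_size = 30L, cut_height = 0.75,
                            gs_min = 0.5, mm_min = 0.5,
                            n_linear = "sqrt", n_product = "sqrt",
                            lasso_grid = NULL) {
  stopifnot(cmi2_threshold >= 0, mi_threshold >= 0, weight_threshold >= 0,
            bins >= 2L, n_bootstraps >= 1L)
  estimator <- match.arg(estimator, c("gaussian", "binned"))
  structure(list(cmi2_threshold = cmi2_threshold, mi_threshold = mi_threshold,
                 weight_threshold = weight_threshold, bins = as.integer(bins),
                 n_bootstraps = as.integer(n_bootstraps),
                 rng_seed = as.integer(rng_seed), estimator = estimator,
                 beta = beta, min_size = as.integer(min_size),
                 cut_height = cut_height, gs_min = gs_min, mm_min = mm_min,
                 n_linear = n_linear, n_product = n_product,
                 lasso_grid = lasso_grid),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML whose keys mirror the [pipeline_config()] arguments; unknown
#' keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Coexpression hub-gene preselection
#'
#' The preselection recipe of the real-data pipeline: similarity and
#' soft-threshold adjacency (picking beta by scale-free fit when not set),
#' module detection, selection of the module whose eigengene is most
#' correlated with the phenotype, and GS/MM hub screening in that module.
#'
#' @param expr Expression matrix.
#' @param labels [phenotype_labels()].
#' @param cfg A [pipeline_config()].
#' @return Character vector of hub gene ids (attribute `"module"` names the
#'   selected module).
#' @export
preselect_hub_genes <- function(expr, labels, cfg = pipeline_config()) {
  beta <- cfg$beta
  if (is.null(beta)) beta <- pick_soft_threshold(expr)$beta
  A <- soft_threshold_adjacency(similarity_matrix(expr), beta)
  modules <- detect_modules(A, min_size = cfg$min_size,
                            cut_height = cfg$cut_height)
  labs <- setdiff(unique(modules$module), "grey")
  if (length(labs) == 0L) {
    .log("preselect_hub_genes: no modules detected; keeping all genes")
    return(rownames(expr))
  }
  y <- .aligned_labels(expr, labels)
  assoc <- vapply(labs, function(mod) {
    eg <- module_eigengene(expr, modules$gene[modules$module == mod])
    if (stats::sd(eg) == 0) 0 else abs(stats::cor(eg, y))
  }, 0)
  chosen <- labs[which.max(assoc)]
  hubs <- hub_genes(expr, modules, labels, chosen,
                    gs_min = cfg$gs_min, mm_min = cfg$mm_min)
  attr(hubs, "module") <- chosen
  hubs
}

#' Run the full inference pipeline
#'
#' With phenotype labels, genes are first narrowed to coexpression hub genes
#' ([preselect_hub_genes()]); without labels (benchmark mode) that stage is
#' skipped and the causal stages run on all genes. The complete graph is then
#' pruned by causal strength ([prune_network()]), isolated genes are dropped,
#' and a signed directed network is inferred among the survivors by ensemble
#' regression ([infer_signed_network()]) with the configured weight cutoff.
#'
#' @param expr Expression matrix (genes x samples).
#' @param cfg A [pipeline_config()].
#' @param labels Optional [phenotype_labels()] enabling the coexpression
#'   stage.
#' @return A list of class `cser_run` with elements `network` (the
#'   [signed_network()]), `pruned` (the undirected causal skeleton), and
#'   `report` (stage-by-stage counts, configuration echo, and wall-clock
#'   seconds per stage).
#' @export
run_cser <- function(expr, cfg = pipeline_config(), labels = NULL) {
  expr <- expression_matrix(expr)
  report <- list(config = unclass(cfg), seed = cfg$rng_seed,
                 n_genes_in = nrow(expr), n_samples = ncol(expr))
  timings <- c()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  genes <- rownames(expr)
  if (!is.null(labels)) {
    genes <- stage("coexpression", function()
      as.character(preselect_hub_genes(expr, labels, cfg)))
    if (length(genes) < 3L) {
      .log("run_cser: fewer than 3 hub genes; keeping all genes for pruning")
      genes <- rownames(expr)
    }
  }
  report$n_hub_genes <- length(genes)
  sub <- expr[genes, , drop = FALSE]

  pruned <- stage("prune", function()
    prune_network(sub, mi_threshold = cfg$mi_threshold,
                  cmi2_threshold = cfg$cmi2_threshold, bins = cfg$bins,
                  estimator = cfg$estimator))
  report$n_edges_order0 <- attr(pruned, "n_edges_order0", exact = TRUE)
  report$n_edges_pruned <- nrow(pruned)

  selected <- select_connected_genes(pruned)
  report$n_genes_selected <- length(selected)

  if (length(selected) < 3L) {
    .log("run_cser: fewer than 3 connected genes; returning empty network")
    network <- signed_network(NULL, nodes = selected)
  } else {
    ecfg <- ensemble_config(n_bootstraps = cfg$n_bootstraps,
                            n_linear = cfg$n_linear, n_product = cfg$n_product,
                            lasso_grid = cfg$lasso_grid,
                            weight_threshold = cfg$weight_threshold,
                            rng_seed = cfg$rng_seed)
    network <- stage("ensemble", function()
      infer_signed_network(sub[selected, , drop = FALSE], selected, ecfg))
  }
  report$n_edges_final <- nrow(network)
  report$timings_sec <- as.list(timings)
  structure(list(network = network, pruned = pruned, report = report),
            class = "cser_run")
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cser_run <- function(x, ...) {
  r <- x$report
  cat("cser pipeline run\n")
  cat(sprintf("  genes in: %d (samples: %d), hub genes: %d\n",
              r$n_genes_in, r$n_samples, r$n_hub_genes))
  cat(sprintf("  causal skeleton: %d edges, %d connected genes\n",
              r$n_edges_pruned, r$n_genes_selected))
  cat(sprintf("  final signed network: %d edges (|w| >= %.2g)\n",
              r$n_edges_final, r$config$weight_threshold))
  invisible(x)
}
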