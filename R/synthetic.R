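# Synthetic benchmarks: signed DAG gold standards plus expression matrices
# simulated from them with linear-Gaussian structural equations and optional
# pairwise-product (nonlinear) effects, emitted in DREAM4-style files.

#' Synthetic benchmark specification
#'
#' @param n_genes Number of genes (>= 3).
#' @param edge_density Probability of including each forward pair of the
#'   random topological order as an edge (default 0.2, a sparse regulatory
#'   regime of average degree about `0.2 * (n_genes - 1)`).
#' @param activation_fraction Probability that an edge is activating
#'   (default 0.5).
#' @param weight_range Interval of absolute edge-weight magnitudes
#'   (default c(0.5, 1.5)).
#' @param noise_sd Standard deviation of the additive Gaussian noise on each
#'   regulated gene (default 0.25).
#' @param nonlinear_fraction Fraction of multi-parent targets receiving one
#'   pairwise-product term of two parents (default 0.2).
#' @param n_samples Number of samples (>= 10; default 500).
#' @param rng_seed Master seed; the gold standard and the expression draw use
#'   substreams derived from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 10L, edge_density = 0.2,
                           activation_fraction = 0.5,
                           weight_range = c(0.5, 1.5), noise_sd = 0.25,
                           nonlinear_fraction = 0.2, n_samples = 500L,
                           rng_seed = 1L) {
  stopifnot(n_genes >= 3L, n_samples >= 10L,
            edge_density > 0 || edge_density == 0, edge_density <= 1,
            activation_fraction >= 0, activation_fraction <= 1,
            length(weight_range) == 2L, all(weight_range > 0),
            weight_range[1L] <= weight_range[2L],
            noise_sd > 0, nonlinear_fraction >= 0, nonlinear_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes), edge_density = edge_density,
                 activation_fraction = activation_fraction,
                 weight_range = weight_range, noise_sd = noise_sd,
                 nonlinear_fraction = nonlinear_fraction,
                 n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a signed DAG gold standard
#'
#' Samples a uniformly random topological order of the genes and includes
#' each forward pair as an edge with probability `edge_density`; weight
#' magnitudes are uniform in `weight_range` and signs are + with probability
#' `activation_fraction`. The result is acyclic by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return A [signed_network()] whose nodes are `G01, G02, ...`.
#' @export
generate_dag <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(.substream_seed(spec$rng_seed, 1L))
  n <- spec$n_genes
  genes <- sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
  topo <- sample(genes)
  reg <- character(); tgt <- character(); w <- numeric()
  if (n >= 2L && spec$edge_density > 0) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (stats::runif(1L) < spec$edge_density) {
          mag <- stats::runif(1L, spec$weight_range[1L], spec$weight_range[2L])
          sgn <- if (stats::runif(1L) < spec$activation_fraction) 1 else -1
          reg <- c(reg, topo[i]); tgt <- c(tgt, topo[j]); w <- c(w, sgn * mag)
        }
      }
    }
  }
  net <- signed_network(
    if (length(reg)) data.frame(regulator = reg, target = tgt, weight = w,
                                stringsAsFactors = FALSE) else NULL,
    nodes = genes)
  attr(net, "topo_order") <- topo
  net
}

#' Simulate expression from a signed DAG
#'
#' In topological order: root genes are standard normal; every regulated
#' gene is the weighted sum of its parents, plus (for targets selected by
#' `nonlinear_fraction` among those with >= 2 parents) one product term
#' `gamma * x_p1 * x_p2` of a random parent pair with `gamma` of random sign
#' and magnitude from `weight_range`, plus Gaussian noise of sd `noise_sd`.
#' Rows are standardized to zero mean and unit variance at the end.
#'
#' @param gold An acyclic [signed_network()].
#' @param spec A [synthetic_spec()].
#' @return An [expression_matrix()] (genes x samples).
#' @export
simulate_expression <- function(gold, spec) {
  stopifnot(inherits(gold, "signed_network"), inherits(spec, "synthetic_spec"))
  genes <- network_nodes(gold)
  g <- igraph::graph_from_data_frame(
    as.data.frame(gold)[, c("regulator", "target"), drop = FALSE],
    directed = TRUE, vertices = genes)
  if (!igraph::is_dag(g)) stop("gold standard must be acyclic", call. = FALSE)
  topo <- igraph::V(g)$name[igraph::topo_sort(g, mode = "out")]
  set.seed(.substream_seed(spec$rng_seed, 2L))
  m <- spec$n_samples
  X <- matrix(0, length(genes), m, dimnames = list(genes, paste0("S", seq_len(m))))
  for (gene in topo) {
    parents <- gold[gold$target == gene, , drop = FALSE]
    if (nrow(parents) == 0L) {
      X[gene, ] <- stats::rnorm(m)
      next
    }
    val <- rep(0, m)
    for (k in seq_len(nrow(parents))) {
      val <- val + parents$weight[k] * X[parents$regulator[k], ]
    }
    if (nrow(parents) >= 2L && stats::runif(1L) < spec$nonlinear_fraction) {
      pair <- sample(parents$regulator, 2L)
      gamma <- sample(c(-1, 1), 1L) *
        stats::runif(1L, spec$weight_range[1L], spec$weight_range[2L])
      val <- val + gamma * X[pair[1L], ] * X[pair[2L], ]
    }
    X[gene, ] <- val + stats::rnorm(m, sd = spec$noise_sd)
  }
  X <- t(scale(t(X)))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  expression_matrix(X)
}

#' Write a benchmark to disk
#'
#' Emits a DREAM4-style expression TSV (samples x genes with a gene-name
#' header and a sample-id column), the signed edge-list TSV, and a YAML
#' manifest recording the full [synthetic_spec()] including the seed, so the
#' benchmark can be regenerated byte-identically.
#'
#' @param gold A [signed_network()].
#' @param expr The matching [expression_matrix()].
#' @param dir Output directory (created if missing).
#' @param spec The [synthetic_spec()] used (written to the manifest).
#' @return Named character vector of the files written, invisibly.
#' @export
emit_benchmark <- function(gold, expr, dir, spec = NULL) {
  stopifnot(setequal(network_nodes(gold), rownames(expr)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             gold = file.path(dir, "gold_standard.tsv"),
             manifest = file.path(dir, "manifest.yaml"))
  write_expression(expr, paths[["expression"]], orientation = "samples_by_genes")
  write_signed_network(gold, paths[["gold"]])
  manifest <- list(format = "cser-benchmark-v1",
                   n_genes = nrow(expr), n_samples = ncol(expr))
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}
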