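# Post-inference analytics: out-degree key-regulator ranking, Spearman
# correlation networks, and maximal-clique centrality (MCC).

#' Rank genes by out-degree
#'
#' Key-regulator ranking: genes sorted by out-degree descending, ties broken
#' lexicographically; the top k are returned (all genes when k exceeds the
#' node count).
#'
#' @param net A [signed_network()].
#' @param k Number of top regulators to return.
#' @return A data.frame with columns `gene`, `out_degree`, in rank order.
#' @export
out_degree_ranking <- function(net, k = 7L) {
  stopifnot(inherits(net, "signed_network"), k >= 1L)
  nodes <- network_nodes(net)
  deg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(net) > 0L) {
    tab <- table(net$regulator)
    deg[names(tab)] <- as.integer(tab)
  }
  ord <- order(-deg, names(deg))
  top <- utils::head(ord, k)
  data.frame(gene = names(deg)[top], out_degree = as.integer(deg[top]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation network
#'
#' Computes Spearman's rho for every row pair of an abundance (or
#' expression) matrix and keeps edges with `|rho| >= r_min` and p <= `alpha`;
#' the signed rho is the edge weight. P-values use the large-sample t
#' approximation, switching to the exact permutation distribution below 10
#' samples. Constant rows yield no edges.
#'
#' @param abundance Matrix with taxa/genes in rows, samples in columns
#'   (>= 3 samples).
#' @param r_min Absolute-correlation threshold (default 0.7).
#' @param alpha P-value threshold (default 0.05).
#' @return An [undirected_network()] with columns `weight` (rho) and `p`.
#' @export
correlation_network <- function(abundance, r_min = 0.7, alpha = 0.05) {
  abundance <- as.matrix(abundance)
  if (ncol(abundance) < 3L) stop("need at least 3 samples", call. = FALSE)
  ids <- rownames(abundance)
  if (is.null(ids)) ids <- paste0("T", seq_len(nrow(abundance)))
  n <- nrow(abundance); m <- ncol(abundance)
  const <- apply(abundance, 1L, function(x) max(x) == min(x))
  if (any(const)) {
    .log("correlation_network: %d constant row(s) have no edges", sum(const))
  }
  rows <- list()
  for (i in seq_len(n - 1L)) {
    if (const[i]) next
    for (j in (i + 1L):n) {
      if (const[j]) next
      ct <- suppressWarnings(
        stats::cor.test(abundance[i, ], abundance[j, ], method = "spearman",
                        exact = m < 10L))
      rho <- unname(ct$estimate)
      if (is.na(rho)) next
      if (abs(rho) >= r_min && ct$p.value <= alpha) {
        rows[[length(rows) + 1L]] <- data.frame(
          node1 = ids[i], node2 = ids[j], weight = rho, p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else NULL
  undirected_network(edges, nodes = ids)
}

#' Maximal-clique centrality (MCC)
#'
#' For each node v, `MCC(v) = sum over cliques C in S(v) of (|C| - 1)!`,
#' where S(v) is by default the set of all maximal cliques of the graph
#' containing v (`cliques = "all"`), or only those of the largest size among
#' them (`cliques = "largest"`). Nodes on no edge score 0.
#'
#' @param net An [undirected_network()].
#' @param cliques `"all"` (default) or `"largest"`.
#' @return A data.frame of class `mcc_table` with columns `node`, `mcc`, and
#'   a list column `clique_sizes`.
#' @export
mcc_scores <- function(net, cliques = c("all", "largest")) {
  cliques <- match.arg(cliques)
  stopifnot(inherits(net, "undirected_network"))
  nodes <- network_nodes(net)
  g <- igraph::graph_from_data_frame(
    as.data.frame(net)[, c("node1", "node2"), drop = FALSE],
    directed = FALSE, vertices = nodes)
  mc <- if (nrow(net) > 0L) igraph::max_cliques(g, min = 2L) else list()
  mc <- lapply(mc, function(v) sort(igraph::V(g)$name[v]))
  score <- stats::setNames(numeric(length(nodes)), nodes)
  sizes <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    mine <- Filter(function(cl) v %in% cl, mc)
    sz <- vapply(mine, length, 0L)
    if (cliques == "largest" && length(sz) > 0L) sz <- sz[sz == max(sz)]
    sizes[[v]] <- sort(sz)
    score[v] <- sum(factorial(sz - 1L))
  }
  out <- data.frame(node = nodes, mcc = as.numeric(score),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$clique_sizes <- unname(sizes)
  class(out) <- c("mcc_table", "data.frame")
  out
}
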