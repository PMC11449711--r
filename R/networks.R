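# Network containers: signed directed networks (inference output and gold
# standards) and undirected networks (causal pruning, correlation networks).

#' Construct a signed directed network
#'
#' Edges are regulator -> target with a nonzero real weight; the sign of the
#' weight encodes the regulation type (+1 activation, -1 repression). At most
#' one edge per ordered pair, no self-loops.
#'
#' @param edges A data.frame with columns `regulator`, `target`, `weight`
#'   (`sign` is derived). May have zero rows.
#' @param nodes Character vector of node ids; defaults to the union of the
#'   genes on the edges.
#' @return An object of class `signed_network`: a data.frame of edges with a
#'   `nodes` attribute.
#' @export
signed_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(regulator = character(), target = character(),
                        weight = numeric(), sign = integer(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(regulator = as.character(edges$regulator),
                        target = as.character(edges$target),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    if (any(!is.finite(edges$weight))) stop("edge weights must be finite", call. = FALSE)
    if (any(edges$weight == 0)) stop("edge weights must be nonzero", call. = FALSE)
    if (any(edges$regulator == edges$target)) stop("self-loops are not allowed", call. = FALSE)
    key <- paste(edges$regulator, edges$target, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate (regulator, target) edge", call. = FALSE)
    edges$sign <- ifelse(edges$weight > 0, 1L, -1L)
    edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$regulator, edges$target)))
  attr(edges, "nodes") <- as.character(nodes)
  class(edges) <- c("signed_network", "data.frame")
  edges
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("Signed directed network: %d nodes, %d edges (%d activating, %d repressing)\n",
              length(attr(x, "nodes")), nrow(x), sum(x$sign == 1L), sum(x$sign == -1L)))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

#' Construct an undirected network
#'
#' Simple symmetric graph used for pruned causal skeletons and correlation
#' networks. Node pairs are stored once with `node1 < node2`.
#'
#' @param edges A data.frame with columns `node1`, `node2` and optionally
#'   `weight` (plus any extra annotation columns, which are kept).
#' @param nodes Character vector of node ids.
#' @return An object of class `undirected_network`.
#' @export
undirected_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(node1 = character(), node2 = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges$node1 <- as.character(edges$node1)
    edges$node2 <- as.character(edges$node2)
    if (is.null(edges$weight)) edges$weight <- 1
    if (any(edges$node1 == edges$node2)) stop("self-loops are not allowed", call. = FALSE)
    swap <- edges$node1 > edges$node2
    if (any(swap)) {
      tmp <- edges$node1[swap]
      edges$node1[swap] <- edges$node2[swap]
      edges$node2[swap] <- tmp
    }
    key <- paste(edges$node1, edges$node2, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edge", call. = FALSE)
    edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$node1, edges$node2)))
  attr(edges, "nodes") <- as.character(nodes)
  class(edges) <- c("undirected_network", "data.frame")
  edges
}

#' @export
print.undirected_network <- function(x, ...) {
  cat(sprintf("Undirected network: %d nodes, %d edges\n",
              length(attr(x, "nodes")), nrow(x)))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

#' Network node set
#' @param net A `signed_network` or `undirected_network`.
#' @return Character vector of node ids.
#' @export
network_nodes <- function(net) attr(net, "nodes")
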