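# Causal-strength scoring with CMI2 and path-consistency pruning of the
# complete gene graph.
#
# CMI2(A,B | C) = [ D_KL(P || P_{A->B}) + D_KL(P || P_{B->A}) ] / 2
# where P is the joint distribution of (A, B, C) and P_{A->B} is the
# "intervention" distribution obtained by severing the direct A -> B
# dependence:  P_{A->B}(a,b,c) = P(a,c) * sum_a' P(b | c,a') P(a').
# Mutual information is the zero-order case (constant conditioner);
# CMI2 decomposes as CMI plus two nonnegative KL terms, so CMI2 >= CMI.
# All information quantities are in nats.

#' Estimate a discrete joint distribution from expression rows
#'
#' Each row is discretized into `bins` equal-frequency (quantile) bins, ties
#' resolved by stable rank (original order); the empirical joint frequency
#' table is normalized to sum to one. A constant row occupies a single bin.
#'
#' @param rows Numeric matrix with 1-3 rows (variables) and m columns
#'   (samples), or a numeric vector for one variable.
#' @param bins Integer >= 2, number of bins per variable.
#' @param estimator Currently only `"binned"`.
#' @return A `joint_distribution`: a probability array with one dimension per
#'   variable.
#' @export
estimate_joint <- function(rows, bins, estimator = "binned") {
  estimator <- match.arg(estimator, "binned")
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  k <- nrow(rows); m <- ncol(rows)
  if (k < 1L || k > 3L) stop("estimate_joint takes 1-3 variables", call. = FALSE)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  if (m < bins) stop("need at least as many samples as bins", call. = FALSE)
  idx <- matrix(0L, k, m)
  for (v in seq_len(k)) {
    x <- rows[v, ]
    if (max(x) == min(x)) {
      .log("estimate_joint: constant variable %d occupies a single bin", v)
      idx[v, ] <- 1L
    } else {
      r <- rank(x, ties.method = "first")
      idx[v, ] <- as.integer(ceiling(r * bins / m))
    }
  }
  counts <- array(0, dim = rep(bins, k))
  flat <- idx[1L, ]
  if (k >= 2L) flat <- flat + (idx[2L, ] - 1L) * bins
  if (k == 3L) flat <- flat + (idx[3L, ] - 1L) * bins * bins
  tab <- tabulate(flat, nbins = bins^k)
  counts[] <- tab / m
  joint_distribution(counts)
}

#' Construct a joint distribution from a probability array
#'
#' @param p Nonnegative numeric array (1-3 dimensions) summing to 1 (within
#'   1e-12 before renormalization).
#' @return A `joint_distribution` object.
#' @export
joint_distribution <- function(p) {
  p <- as.array(p)
  if (length(dim(p)) > 3L) stop("at most 3 variables", call. = FALSE)
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-12) stop("probabilities must sum to 1", call. = FALSE)
  class(p) <- c("joint_distribution", class(p))
  p
}

#' @keywords internal
.jd_arity <- function(P, need, op) {
  d <- dim(P)
  if (length(d) != need) {
    stop(sprintf("%s requires a %d-variable distribution", op, need), call. = FALSE)
  }
  d
}

#' Mutual information of a 2-variable joint distribution
#'
#' `MI = sum_ab p(a,b) ln[ p(a,b) / (p(a) p(b)) ]` in nats, with the
#' convention `0 ln(0/x) = 0`.
#'
#' @param P A 2-variable `joint_distribution`.
#' @return Nonnegative scalar (clamped at 0 against roundoff).
#' @export
mutual_information <- function(P) {
  .jd_arity(P, 2L, "mutual_information")
  pa <- rowSums(P); pb <- colSums(P)
  pp <- outer(pa, pb)
  pos <- P > 0
  max(0, sum(P[pos] * log(P[pos] / pp[pos])))
}

#' Conditional mutual information of a 3-variable joint distribution
#'
#' `CMI(A;B|C) = sum p(a,b,c) ln[ p(c) p(a,b,c) / (p(a,c) p(b,c)) ]`.
#'
#' @param P A 3-variable `joint_distribution` over (A, B, C).
#' @return Nonnegative scalar.
#' @export
conditional_mutual_information <- function(P) {
  d <- .jd_arity(P, 3L, "conditional_mutual_information")
  pac <- apply(P, c(1L, 3L), sum)
  pbc <- apply(P, c(2L, 3L), sum)
  pc <- apply(P, 3L, sum)
  tot <- 0
  for (c_ in seq_len(d[3L])) {
    slice <- P[, , c_, drop = FALSE]
    dim(slice) <- d[1:2]
    pos <- slice > 0
    if (!any(pos)) next
    denom <- outer(pac[, c_], pbc[, c_])
    tot <- tot + sum(slice[pos] * log(pc[c_] * slice[pos] / denom[pos]))
  }
  max(0, tot)
}

#' Intervention distribution of a 3-variable joint distribution
#'
#' For direction `"A->B"` returns
#' `q(a,b,c) = p(a,c) * sum_a' p(b | c, a') p(a')`, the joint distribution
#' with the direct A -> B dependence severed; `p(b | c, a')` is taken as 0
#' when `p(a',c) = 0`. `"B->A"` swaps the roles of A and B.
#'
#' @param P A 3-variable `joint_distribution` over (A, B, C).
#' @param direction `"A->B"` or `"B->A"`.
#' @return A probability array of the same shape (a `joint_distribution`
#'   whenever the support condition makes it sum to exactly 1).
#' @export
intervention_distribution <- function(P, direction = c("A->B", "B->A")) {
  direction <- match.arg(direction)
  d <- .jd_arity(P, 3L, "intervention_distribution")
  q <- array(0, dim = d)
  if (direction == "A->B") {
    pac <- apply(P, c(1L, 3L), sum)          # p(a, c)
    pa <- apply(P, 1L, sum)                  # p(a)
    for (c_ in seq_len(d[3L])) {
      # g(b) = sum_a' p(b | c, a') p(a')
      g <- rep(0, d[2L])
      for (a2 in seq_len(d[1L])) {
        if (pac[a2, c_] > 0) g <- g + P[a2, , c_] / pac[a2, c_] * pa[a2]
      }
      q[, , c_] <- outer(pac[, c_], g)
    }
  } else {
    pbc <- apply(P, c(2L, 3L), sum)          # p(b, c)
    pb <- apply(P, 2L, sum)                  # p(b)
    for (c_ in seq_len(d[3L])) {
      h <- rep(0, d[1L])                     # h(a) = sum_b' p(a | c, b') p(b')
      for (b2 in seq_len(d[2L])) {
        if (pbc[b2, c_] > 0) h <- h + P[, b2, c_] / pbc[b2, c_] * pb[b2]
      }
      q[, , c_] <- outer(h, pbc[, c_])
    }
  }
  class(q) <- c("joint_distribution", class(q))
  q
}

#' Kullback-Leibler divergence between distributions of identical shape
#'
#' `D(P || Q) = sum p ln(p/q)` with `0 ln(0/q) = 0`; a cell with `p > 0` and
#' `q = 0` yields `+Inf` (logged).
#'
#' @param P,Q Probability arrays of identical shape.
#' @return Nonnegative scalar, possibly `Inf`.
#' @export
kl_divergence <- function(P, Q) {
  if (!identical(dim(as.array(P)), dim(as.array(Q)))) {
    stop("distributions have different shapes", call. = FALSE)
  }
  p <- as.numeric(P); q <- as.numeric(Q)
  pos <- p > 0
  if (any(pos & q == 0)) {
    .log("kl_divergence: P-support outside Q-support, divergence is +Inf")
    return(Inf)
  }
  max(0, sum(p[pos] * log(p[pos] / q[pos])))
}

#' Conditional mutual inclusive information (CMI2)
#'
#' The causal-strength score: the average of the KL divergences from the
#' joint distribution to the two intervention distributions. With a constant
#' conditioner it reduces to mutual information (order 0), and it is never
#' smaller than the conditional mutual information.
#'
#' @param P A 3-variable `joint_distribution` over (A, B, C); pass a
#'   single-bin C for the zero-order score.
#' @return Nonnegative scalar in nats.
#' @export
cmi2 <- function(P) {
  .jd_arity(P, 3L, "cmi2")
  (kl_divergence(P, intervention_distribution(P, "A->B")) +
     kl_divergence(P, intervention_distribution(P, "B->A"))) / 2
}

# Convenience: CMI2 between two expression rows given an optional conditioner
# row. NULL conditioner = order 0, which equals mutual information.
#' @rdname cmi2
#' @param x,y Numeric expression rows of equal length.
#' @param z Optional conditioner row (order 1); `NULL` for order 0.
#' @param bins Bins per variable for [estimate_joint()] (binned estimator).
#' @param estimator `"gaussian"` (closed form for continuous data, the
#'   default) or `"binned"` (exact computation on the quantile-binned table).
#' @export
cmi2_score <- function(x, y, z = NULL, bins = 3L,
                       estimator = c("gaussian", "binned")) {
  estimator <- match.arg(estimator)
  if (estimator == "gaussian") {
    return(if (is.null(z)) .gauss_mi(x, y) else .gauss_cmi2(x, y, z))
  }
  m <- length(x)
  rows <- rbind(x, y, if (is.null(z)) rep(0, m) else z)
  P3 <- estimate_joint(rows, bins)
  if (is.null(z)) {
    # constant conditioner occupies bin 1 only; keep the single slice
    P3 <- joint_distribution(array(P3[, , 1L], dim = c(bins, bins, 1L)))
  }
  cmi2(P3)
}

# ---- Gaussian causal-strength estimator -----------------------------------
#
# For jointly Gaussian (A, B, C) the intervention distribution has a closed
# form: p(b | c, a') is Gaussian with mean linear in (c, a'), so integrating
# over a' ~ p(a) leaves P_{A->B}(a,b,c) = p(a,c) * N(b; beta_c c, tau^2)
# with tau^2 = var(B | A, C) + beta_a^2 var(A) -- again a zero-mean Gaussian.
# The KL divergence between two zero-mean Gaussians is
# (tr(Sq^-1 Sp) - d + ln det Sq - ln det Sp) / 2, giving the causal score
# without any discretization. Order 0 reduces to -ln(1 - rho^2) / 2.

#' @keywords internal
.gauss_mi <- function(x, y) {
  r2 <- stats::cor(x, y)^2
  r2 <- min(r2, 1 - 1e-12)
  max(0, -0.5 * log1p(-r2))
}

# KL(P || Q) for zero-mean Gaussians with covariances Sp, Sq
#' @keywords internal
.gauss_kl <- function(Sp, Sq) {
  d <- nrow(Sp)
  ridge <- diag(d) * 1e-12 * mean(diag(Sp))
  Sp <- Sp + ridge; Sq <- Sq + ridge
  ldp <- determinant(Sp, logarithm = TRUE)$modulus[[1L]]
  ldq <- determinant(Sq, logarithm = TRUE)$modulus[[1L]]
  max(0, 0.5 * (sum(diag(solve(Sq, Sp))) - d + ldq - ldp))
}

# One directed KL term: severs the direct A -> B link. The coefficient of A
# in the regression of B on (A, C) enters the intervention variance; when A
# and C are nearly collinear its least-squares estimate is dominated by
# noise (variance inflated by 1/(1 - R^2_{A|C})), which would leak into the
# score. The coefficient is therefore kept only when BIC prefers the model
# including A; otherwise the severed link is treated as absent and the term
# reduces exactly to the conditional mutual information.
#' @keywords internal
.gauss_kl_dir <- function(S, a, b, c_, m) {
  beta <- solve(S[c(a, c_), c(a, c_)], S[c(a, c_), b])
  s2_full <- max(S[b, b] - sum(S[b, c(a, c_)] * beta), 1e-300)
  s2_red <- max(S[b, b] - S[b, c_]^2 / S[c_, c_], 1e-300)
  if (m * log(s2_red / s2_full) <= log(m)) {
    beta <- c(0, S[b, c_] / S[c_, c_])      # BIC drops A from the regression
    s2_full <- s2_red
  }
  tau2 <- s2_full + beta[1L]^2 * S[a, a]
  Sq <- S
  Sq[b, b] <- beta[2L]^2 * S[c_, c_] + tau2
  Sq[a, b] <- Sq[b, a] <- beta[2L] * S[a, c_]
  Sq[b, c_] <- Sq[c_, b] <- beta[2L] * S[c_, c_]
  .gauss_kl(S, Sq)
}

#' @keywords internal
.gauss_cmi2 <- function(x, y, z) {
  m <- length(x)
  S <- stats::cov(cbind(x, y, z))
  S <- S + diag(3L) * 1e-12 * mean(diag(S))   # guard exact collinearity
  (.gauss_kl_dir(S, 1L, 2L, 3L, m) + .gauss_kl_dir(S, 2L, 1L, 3L, m)) / 2
}

#' Prune the complete gene graph by causal strength
#'
#' Three steps: (1) start from the complete graph on all genes; (2) remove
#' every pair whose mutual information falls below `mi_threshold`; (3) for
#' each surviving edge (i, j), score `max_z CMI2(i, j | z)` over the common
#' neighbors z of i and j in the step-2 graph and remove the edge when
#' conditioners exist and the score falls below `cmi2_threshold`. Step-3
#' decisions are all taken against the frozen step-2 graph (no cascade), with
#' edges visited in lexicographic gene-id order, so the result does not
#' depend on gene input order.
#'
#' @param expr Expression matrix (genes x samples).
#' @param mi_threshold Order-0 removal threshold in nats (default 0.03).
#' @param cmi2_threshold Order-1 removal threshold in nats (default 0.03).
#' @param bins Bins per variable for the binned estimator.
#' @param estimator `"gaussian"` (default; closed-form scores suited to
#'   continuous expression data) or `"binned"` (scores computed exactly on
#'   quantile-binned joint tables).
#' @return An [undirected_network()] whose `weight` column carries the final
#'   per-edge score and whose `order` column records the order (0 or 1) at
#'   which the score was computed; the node set keeps the input gene order.
#' @export
prune_network <- function(expr, mi_threshold = 0.03, cmi2_threshold = 0.03,
                          bins = 3L, estimator = c("gaussian", "binned")) {
  expr <- expression_matrix(expr)
  estimator <- match.arg(estimator)
  .assert_scalar_number(mi_threshold, "mi_threshold", min = 0)
  .assert_scalar_number(cmi2_threshold, "cmi2_threshold", min = 0)
  bins <- as.integer(bins)
  n <- nrow(expr); m <- ncol(expr)
  if (bins > m) stop("bins must not exceed the number of samples", call. = FALSE)
  genes <- rownames(expr)

  # step 1 + 2: order-0 mutual information on every pair
  constant <- apply(expr, 1L, function(x) max(x) == min(x))
  if (any(constant)) {
    .log("prune_network: %d constant gene(s) have zero mutual information",
         sum(constant))
  }
  mi <- matrix(0, n, n)
  if (estimator == "binned") {
    disc <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      disc[i, ] <- if (constant[i]) rep(1L, m) else
        as.integer(ceiling(rank(expr[i, ], ties.method = "first") * bins / m))
    }
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (constant[i] || constant[j]) next
      mi[i, j] <- mi[j, i] <- if (estimator == "gaussian") {
        .gauss_mi(expr[i, ], expr[j, ])
      } else {
        tab <- tabulate(disc[i, ] + (disc[j, ] - 1L) * bins, nbins = bins * bins) / m
        mutual_information(joint_distribution(array(tab, dim = c(bins, bins))))
      }
    }
  }
  adj <- mi >= mi_threshold
  diag(adj) <- FALSE
  n_mi_edges <- sum(adj) / 2L
  .log("prune_network: %d genes, %d/%d edges pass order-0 threshold %.3g",
       n, n_mi_edges, n * (n - 1L) / 2L, mi_threshold)

  # step 3: first-order CMI2 against the frozen step-2 graph
  ord_genes <- order(genes)
  edges <- list()
  for (oi in seq_len(n)) {
    i <- ord_genes[oi]
    for (oj in seq_len(n)) {
      j <- ord_genes[oj]
      if (oj <= oi || !adj[i, j]) next
      zs <- which(adj[i, ] & adj[j, ])
      zs <- setdiff(zs, c(i, j))
      if (length(zs) == 0L) {
        edges[[length(edges) + 1L]] <-
          list(i = genes[i], j = genes[j], score = mi[i, j], order = 0L)
        next
      }
      best <- -Inf
      for (z in zs[order(genes[zs])]) {
        best <- max(best, if (estimator == "gaussian") {
          .gauss_cmi2(expr[i, ], expr[j, ], expr[z, ])
        } else {
          cmi2(estimate_joint(expr[c(i, j, z), , drop = FALSE], bins))
        })
      }
      if (best >= cmi2_threshold) {
        edges[[length(edges) + 1L]] <-
          list(i = genes[i], j = genes[j], score = best, order = 1L)
      }
    }
  }
  kept <- if (length(edges) == 0L) {
    data.frame(node1 = character(), node2 = character(), weight = numeric(),
               order = integer(), stringsAsFactors = FALSE)
  } else {
    data.frame(node1 = vapply(edges, `[[`, "", "i"),
               node2 = vapply(edges, `[[`, "", "j"),
               weight = vapply(edges, `[[`, 0, "score"),
               order = vapply(edges, `[[`, 0L, "order"),
               stringsAsFactors = FALSE)
  }
  .log("prune_network: %d edges retained after order-1 pruning (threshold %.3g)",
       nrow(kept), cmi2_threshold)
  net <- undirected_network(kept, nodes = genes)
  attr(net, "n_edges_order0") <- as.integer(n_mi_edges)
  net
}

#' Genes that remain connected after pruning
#'
#' Drops isolated genes (degree 0) from the pruned graph; the remaining genes
#' keep their original input order.
#'
#' @param net An [undirected_network()].
#' @return Character vector of connected gene ids.
#' @export
select_connected_genes <- function(net) {
  stopifnot(inherits(net, "undirected_network"))
  nodes <- network_nodes(net)
  nodes[nodes %in% c(net$node1, net$node2)]
}
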