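# Bagged-Lasso ensemble over polynomial features: per-target regression
# tasks whose averaged signed coefficients become directed activation /
# repression edge weights.

#' Ensemble configuration
#'
#' @param n_bootstraps Number of bootstrap resamples B per target.
#' @param n_linear Linear features per bootstrap: an integer or `"sqrt"`
#'   (ceil(sqrt(p)) for p candidate regulators).
#' @param n_product Pairwise-product features per bootstrap: an integer or
#'   `"sqrt"`; products are formed from the bootstrap's selected linear
#'   regulators so every coefficient is attributable to in-model genes.
#' @param lasso_grid Optional vector of penalty values; `NULL` builds 20
#'   log-spaced values per bootstrap from `lambda_max` down to
#'   `lambda_max/1000`. The penalty is chosen by minimum BIC.
#' @param weight_threshold Absolute-weight cutoff for retaining an edge.
#' @param rng_seed Master seed; per-(target, bootstrap) substreams are derived
#'   from it so results do not depend on target evaluation order.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_bootstraps = 500L, n_linear = "sqrt",
                            n_product = "sqrt", lasso_grid = NULL,
                            weight_threshold = 0.5, rng_seed = 1L) {
  stopifnot(n_bootstraps >= 1L, weight_threshold >= 0)
  if (!is.null(lasso_grid)) stopifnot(all(lasso_grid > 0))
  structure(list(n_bootstraps = as.integer(n_bootstraps),
                 n_linear = n_linear, n_product = n_product,
                 lasso_grid = lasso_grid,
                 weight_threshold = weight_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "ensemble_config")
}

#' @keywords internal
.resolve_count <- function(x, p, name, max_allowed, warn = TRUE) {
  k <- if (identical(x, "sqrt")) ceiling(sqrt(p)) else as.integer(x)
  if (k > max_allowed) {
    if (warn) {
      warning(sprintf("%s = %d exceeds available features, clamped to %d",
                      name, k, max_allowed), call. = FALSE)
    }
    k <- max_allowed
  }
  as.integer(k)
}

#' Build one bootstrap design for a target gene
#'
#' Resamples the m samples with replacement, selects `n_linear` distinct
#' candidate regulators uniformly at random (linear features) and `n_product`
#' distinct unordered pairs among them (elementwise-product features), then
#' standardizes every feature column and the target response to zero mean and
#' unit variance within the bootstrap. Constant columns are dropped.
#'
#' @param expr Expression matrix.
#' @param target Target gene id.
#' @param candidates Candidate regulator ids (must exclude the target).
#' @param cfg An [ensemble_config()].
#' @return A list with the standardized design `X`, the response `y`, and
#'   `descriptors`: a list of the constituent gene id(s) per column. Uses the
#'   current RNG state; seed it for determinism.
#' @export
build_bootstrap_features <- function(expr, target, candidates = NULL,
                                     cfg = ensemble_config()) {
  if (is.null(candidates)) candidates <- setdiff(rownames(expr), target)
  if (target %in% candidates) stop("candidates must exclude the target", call. = FALSE)
  p <- length(candidates)
  if (p < 2L) stop("need at least 2 candidate regulators", call. = FALSE)
  m <- ncol(expr)
  n1 <- .resolve_count(cfg$n_linear, p, "n_linear", p)
  # fewer pairs than requested products is the normal small-p case
  n2 <- .resolve_count(cfg$n_product, p, "n_product", choose(n1, 2L),
                       warn = FALSE)

  rows <- sample.int(m, m, replace = TRUE)
  lin <- sort(sample(candidates, n1))
  descriptors <- as.list(lin)
  X <- t(expr[lin, rows, drop = FALSE])
  if (n2 > 0L && n1 >= 2L) {
    pair_idx <- utils::combn(n1, 2L)
    pick <- sample.int(ncol(pair_idx), n2)
    for (k in pick) {
      a <- lin[pair_idx[1L, k]]; b <- lin[pair_idx[2L, k]]
      X <- cbind(X, expr[a, rows] * expr[b, rows])
      descriptors[[length(descriptors) + 1L]] <- c(a, b)
    }
  }
  y <- expr[target, rows]

  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) .log("dropping %d constant feature column(s)", sum(!keep))
  X <- X[, keep, drop = FALSE]
  descriptors <- descriptors[keep]
  X <- scale(X)
  y_sd <- stats::sd(y)
  y <- if (y_sd > 0) as.numeric(scale(y)) else y - mean(y)
  list(X = X, y = y, descriptors = descriptors, linear = lin,
       degenerate = y_sd == 0 || ncol(X) == 0L)
}

# Lasso on a standardized design with the penalty picked by minimum BIC over
# a grid. Returns the coefficient vector at the selected penalty.
#' @keywords internal
.lasso_bic <- function(X, y, lasso_grid = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(lasso_grid)) {
    lmax <- max(abs(crossprod(X, y)) / n, .Machine$double.eps)
    lasso_grid <- exp(seq(log(lmax), log(lmax / 1000), length.out = 20L))
  }
  lasso_grid <- sort(lasso_grid, decreasing = TRUE)
  if (p == 1L) {
    # soft-thresholded simple regression; same objective as glmnet for p = 1
    bhat <- sum(X[, 1L] * y) / n
    beta <- sign(bhat) * pmax(abs(bhat) - lasso_grid, 0)
    rss <- vapply(beta, function(b) sum((y - X[, 1L] * b)^2), 0)
    bic <- n * log(pmax(rss / n, 1e-300)) + (beta != 0) * log(n)
    return(beta[which.min(bic)])
  }
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = lasso_grid, standardize = FALSE,
                        intercept = FALSE)
  beta <- as.matrix(fit$beta)
  resid <- y - X %*% beta
  rss <- colSums(resid^2)
  df <- colSums(beta != 0)
  bic <- n * log(pmax(rss / n, 1e-300)) + df * log(n)
  beta[, which.min(bic)]
}

#' Ensemble weight vector for one target gene
#'
#' Runs B bootstraps; in each, fits a Lasso on the bootstrap design from
#' [build_bootstrap_features()] with a BIC-selected penalty, and attributes
#' each fitted coefficient to genes: a linear column wholly to its gene, a
#' product column half to each constituent. A regulator's final weight is the
#' sum of its attributed coefficients across the bootstraps in which it was a
#' selected linear regulator, divided by that support count (0 support gives
#' weight 0).
#'
#' @param expr Expression matrix.
#' @param target Target gene id.
#' @param candidates Candidate regulators (default: all other genes).
#' @param cfg An [ensemble_config()].
#' @param target_index Integer used to derive the per-target RNG substream;
#'   defaults to the target's position among the sorted candidate-plus-target
#'   gene set.
#' @return A data.frame of class `weight_vector` with columns `regulator`,
#'   `weight`, `support`, and the target id as attribute `target`.
#' @export
fit_target_weights <- function(expr, target, candidates = NULL,
                               cfg = ensemble_config(), target_index = NULL) {
  if (is.null(candidates)) candidates <- setdiff(rownames(expr), target)
  if (is.null(target_index)) {
    target_index <- match(target, sort(c(candidates, target)))
  }
  p <- length(candidates)
  coef_sum <- stats::setNames(numeric(p), candidates)
  support <- stats::setNames(integer(p), candidates)
  skipped <- 0L
  for (b in seq_len(cfg$n_bootstraps)) {
    set.seed(.substream_seed(cfg$rng_seed, target_index, b))
    bs <- build_bootstrap_features(expr, target, candidates, cfg)
    if (bs$degenerate) {
      skipped <- skipped + 1L
      next
    }
    beta <- .lasso_bic(bs$X, bs$y, cfg$lasso_grid)
    support[bs$linear] <- support[bs$linear] + 1L
    for (k in seq_along(beta)) {
      if (beta[k] == 0) next
      genes_k <- bs$descriptors[[k]]
      share <- beta[k] / length(genes_k)
      coef_sum[genes_k] <- coef_sum[genes_k] + share
    }
  }
  if (skipped > 0L) .log("target %s: %d degenerate bootstrap(s) skipped", target, skipped)
  weight <- ifelse(support > 0L, coef_sum / pmax(support, 1L), 0)
  out <- data.frame(regulator = candidates, weight = as.numeric(weight),
                    support = as.integer(support), stringsAsFactors = FALSE)
  attr(out, "target") <- target
  class(out) <- c("weight_vector", "data.frame")
  out
}

#' Infer a signed directed network by ensemble regression
#'
#' Treats every candidate gene as a regression target with all remaining
#' candidates as potential regulators, runs [fit_target_weights()] per
#' target, and keeps directed edges whose absolute averaged weight reaches
#' `cfg$weight_threshold`; the weight's sign gives the regulation type
#' (+ activation, - repression). Deterministic given `cfg$rng_seed`.
#'
#' @param expr Expression matrix.
#' @param candidates Gene ids acting as both regulators and targets
#'   (default: all genes).
#' @param cfg An [ensemble_config()].
#' @param full_weights If `TRUE`, attach the full pre-threshold weight table
#'   as attribute `"weights"`.
#' @return A [signed_network()] on the candidate genes.
#' @export
infer_signed_network <- function(expr, candidates = NULL,
                                 cfg = ensemble_config(),
                                 full_weights = FALSE) {
  expr <- expression_matrix(expr)
  if (is.null(candidates)) candidates <- rownames(expr)
  if (!all(candidates %in% rownames(expr))) {
    stop("candidates must be genes of the expression matrix", call. = FALSE)
  }
  if (length(candidates) < 3L) stop("need at least 3 candidate genes", call. = FALSE)
  ord <- sort(candidates)
  tables <- vector("list", length(ord))
  for (t_idx in seq_along(ord)) {
    target <- ord[t_idx]
    wv <- fit_target_weights(expr, target, setdiff(ord, target), cfg,
                             target_index = t_idx)
    wv$target <- target
    tables[[t_idx]] <- as.data.frame(wv)
  }
  all_w <- do.call(rbind, tables)
  keep <- abs(all_w$weight) >= cfg$weight_threshold & all_w$weight != 0
  net <- signed_network(data.frame(regulator = all_w$regulator[keep],
                                   target = all_w$target[keep],
                                   weight = all_w$weight[keep],
                                   stringsAsFactors = FALSE),
                        nodes = ord)
  .log("infer_signed_network: %d/%d directed weights pass |w| >= %.3g",
       sum(keep), nrow(all_w), cfg$weight_threshold)
  if (full_weights) attr(net, "weights") <- all_w
  net
}
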