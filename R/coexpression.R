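# WGCNA-style coexpression preselection: correlation similarity, soft
# thresholding, scale-free fit, hierarchical module detection, and GS/MM
# hub-gene screening.

# deterministic size-ranked module label sequence (WGCNA color order, then
# numbered fallbacks)
.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Pearson similarity matrix
#'
#' `s_ij = cor(x_i, x_j)` across samples, for every gene pair.
#'
#' @param expr Expression matrix (genes x samples).
#' @return Symmetric n x n correlation matrix with unit diagonal.
#' @export
similarity_matrix <- function(expr) {
  expr <- expression_matrix(expr)
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  S <- stats::cor(t(expr))
  diag(S) <- 1
  S
}

#' Soft-threshold adjacency
#'
#' `a_ij = |s_ij|^beta` (unsigned network). The absolute value leaves even
#' powers unchanged and keeps odd powers in `[0, 1]`.
#'
#' @param S Similarity matrix from [similarity_matrix()].
#' @param beta Positive integer soft threshold.
#' @return Adjacency matrix with entries in `[0, 1]` and attribute `beta`.
#' @export
soft_threshold_adjacency <- function(S, beta) {
  if (length(beta) != 1L || beta < 1) stop("beta must be >= 1", call. = FALSE)
  A <- abs(S)^beta
  attr(A, "beta") <- beta
  A
}

# Scale-free topology fit: histogram the connectivities over equal-width
# bins of log10(k) and regress log10(frequency) on the bin-mean log10(k);
# the signed fit is -sign(slope) * R^2 so a decaying degree distribution
# scores positively.
#' @keywords internal
.scale_free_fit <- function(A, n_breaks = 10L) {
  k <- rowSums(A) - diag(A)          # connectivity excluding self
  k <- k[k > 1e-12]
  out_na <- c(r2 = NA_real_, slope = NA_real_,
              mean_k = if (length(k)) mean(k) else NA_real_)
  if (length(k) < 3L) return(out_na)
  lk <- log10(k)
  if (diff(range(lk)) < 1e-9) return(out_na)
  bin <- cut(lk, breaks = n_breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(lk)
  kmean <- tapply(lk, bin, mean)
  ok <- freq > 0 & !is.na(kmean)
  if (sum(ok) < 3L) return(out_na)
  fit <- stats::lm(log10(freq[ok]) ~ kmean[ok])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- stats::coef(fit)[[2L]]
  c(r2 = -sign(slope) * r2, slope = slope, mean_k = mean(k))
}

#' Choose the soft threshold for scale-free topology
#'
#' For each candidate beta, computes the adjacency, per-gene connectivity
#' `k_i = sum_j a_ij`, and the signed scale-free fit: the R-squared of
#' `log10(frequency)` on `log10(k)` over 10 logarithmic connectivity bins,
#' signed positively when the slope is negative (the scale-free direction).
#' Returns the smallest beta whose signed R-squared reaches `r2_min`, else
#' the argmax with a warning.
#'
#' @param expr Expression matrix.
#' @param candidates Candidate integer betas (default 1:20).
#' @param r2_min Signed R-squared acceptance level (default 0.80).
#' @return A list with `beta` and `fit_table` (beta, signed R2, slope, mean
#'   connectivity).
#' @export
pick_soft_threshold <- function(expr, candidates = 1:20, r2_min = 0.80) {
  if (length(candidates) == 0L) stop("no candidate betas", call. = FALSE)
  S <- similarity_matrix(expr)
  rows <- lapply(candidates, function(b) {
    st <- .scale_free_fit(soft_threshold_adjacency(S, b))
    data.frame(beta = b, signed_r2 = st[["r2"]], slope = st[["slope"]],
               mean_connectivity = st[["mean_k"]])
  })
  fit_table <- do.call(rbind, rows)
  ok <- which(!is.na(fit_table$signed_r2) & fit_table$signed_r2 >= r2_min)
  if (length(ok) > 0L) {
    beta <- fit_table$beta[ok[1L]]
  } else {
    if (all(is.na(fit_table$signed_r2))) {
      stop("scale-free fit undefined for every candidate", call. = FALSE)
    }
    beta <- fit_table$beta[which.max(fit_table$signed_r2)]
    warning(sprintf(
      "no candidate reaches signed R^2 >= %.2f; falling back to argmax (beta = %d)",
      r2_min, beta), call. = FALSE)
  }
  .log("pick_soft_threshold: beta = %d", beta)
  list(beta = beta, fit_table = fit_table)
}

#' Detect coexpression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `d_ij = 1 - a_ij`, cut at a fixed height; clusters smaller than `min_size`
#' are relabeled "grey" (unassigned). Labels are deterministic size-ranked
#' color names (ties broken by the lexicographically smallest member gene),
#' so the assignment does not depend on gene input order.
#'
#' @param A Adjacency matrix from [soft_threshold_adjacency()].
#' @param min_size Minimum module size (default 30).
#' @param cut_height Static tree-cut height on the dissimilarity dendrogram
#'   (default 0.75).
#' @return A data.frame of class `module_assignment` with columns `gene` and
#'   `module`.
#' @export
detect_modules <- function(A, min_size = 30L, cut_height = 0.75) {
  if (min_size < 1L) stop("min_size must be >= 1", call. = FALSE)
  genes <- rownames(A)
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(A)))
  d <- 1 - A
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= min_size]
  # deterministic labels: order clusters by size desc, then smallest gene id
  first_gene <- vapply(keep_cl, function(g) min(genes[cl == as.integer(g)]), "")
  ord <- keep_cl[order(-as.integer(sizes[keep_cl]), first_gene)]
  labels <- c(.MODULE_COLORS, paste0("module", seq_len(max(0L, length(ord) - length(.MODULE_COLORS)))))
  module <- rep("grey", length(genes))
  for (i in seq_along(ord)) {
    module[cl == as.integer(ord[i])] <- labels[i]
  }
  out <- data.frame(gene = genes, module = module, stringsAsFactors = FALSE)
  class(out) <- c("module_assignment", "data.frame")
  .log("detect_modules: %d modules, %d genes unassigned (grey)",
       length(ord), sum(module == "grey"))
  out
}

#' Module eigengene
#'
#' First principal-component score vector of the module's standardized
#' expression, sign-oriented to correlate positively with the module's mean
#' expression profile.
#'
#' @param expr Expression matrix.
#' @param genes Gene ids of one module.
#' @return Numeric vector of length m (one score per sample).
#' @export
module_eigengene <- function(expr, genes) {
  sub <- expr[genes, , drop = FALSE]
  std <- t(scale(t(sub)))
  std[is.na(std)] <- 0
  sv <- svd(std, nu = 0L, nv = 1L)
  eg <- sv$v[, 1L]
  mean_profile <- colMeans(sub)
  if (stats::sd(mean_profile) > 0 && stats::cor(eg, mean_profile) < 0) eg <- -eg
  eg
}

#' Gene significance and module membership per gene
#'
#' GS(g) is the absolute Pearson correlation of gene g's expression with the
#' 0/1 phenotype vector; MM(g) is the absolute Pearson correlation with the
#' eigengene of g's module (NA for grey genes).
#'
#' @param expr Expression matrix.
#' @param modules A `module_assignment` from [detect_modules()].
#' @param labels [phenotype_labels()] covering the expression samples.
#' @return A data.frame with columns `gene`, `module`, `GS`, `MM`.
#' @export
module_scores <- function(expr, modules, labels) {
  expr <- expression_matrix(expr)
  y <- .aligned_labels(expr, labels)
  if (length(unique(y)) < 2L) {
    stop("phenotype has a single class; gene significance is undefined", call. = FALSE)
  }
  idx <- match(modules$gene, rownames(expr))
  if (anyNA(idx)) stop("module genes missing from expression matrix", call. = FALSE)
  gs <- vapply(idx, function(i) {
    if (stats::sd(expr[i, ]) == 0) return(0)
    abs(stats::cor(expr[i, ], y))
  }, 0)
  mm <- rep(NA_real_, nrow(modules))
  for (mod in setdiff(unique(modules$module), "grey")) {
    gmask <- modules$module == mod
    eg <- module_eigengene(expr, modules$gene[gmask])
    mm[gmask] <- vapply(idx[gmask], function(i) {
      if (stats::sd(expr[i, ]) == 0) return(0)
      abs(stats::cor(expr[i, ], eg))
    }, 0)
  }
  data.frame(gene = modules$gene, module = modules$module, GS = gs, MM = mm,
             stringsAsFactors = FALSE)
}

#' Screen hub genes in a module
#'
#' Returns the genes of `module_label` with gene significance above `gs_min`
#' and module membership above `mm_min` (both one-sided thresholds on
#' absolute correlations).
#'
#' @inheritParams module_scores
#' @param module_label Module to screen.
#' @param gs_min,mm_min Thresholds (defaults 0.5, the standard screen).
#' @return Character vector of hub gene ids, with the full score table as
#'   attribute `"scores"`.
#' @export
hub_genes <- function(expr, modules, labels, module_label,
                      gs_min = 0.5, mm_min = 0.5) {
  if (!module_label %in% modules$module) {
    stop("module '", module_label, "' not present", call. = FALSE)
  }
  sc <- module_scores(expr, modules, labels)
  sel <- sc$module == module_label & sc$GS > gs_min & sc$MM > mm_min
  sel[is.na(sel)] <- FALSE
  hubs <- sc$gene[sel]
  .log("hub_genes: %d/%d genes in module '%s' pass GS > %.2g and MM > %.2g",
       length(hubs), sum(sc$module == module_label), module_label, gs_min, mm_min)
  attr(hubs, "scores") <- sc
  hubs
}
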