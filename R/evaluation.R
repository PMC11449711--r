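# Evaluation against signed gold standards and the differential-expression
# screen.

#' Sign-classification confusion counts
#'
#' Predicted edges are matched to gold edges by exact (regulator, target)
#' direction. Among matched pairs: predicted + / gold + is a true positive
#' (activation correctly inferred), predicted - / gold - a true negative
#' (repression correctly inferred), predicted + / gold - a false positive,
#' predicted - / gold + a false negative. Predicted edges absent from the
#' gold standard and gold edges not recovered are tallied separately and do
#' not enter the accuracy denominator.
#'
#' @param pred,gold [signed_network()] objects sharing a gene namespace.
#' @return A list of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN`, `n_pred_unmatched`, `n_gold_unrecovered`.
#' @export
sign_confusion <- function(pred, gold) {
  pk <- paste(pred$regulator, pred$target, sep = "\r")
  gk <- paste(gold$regulator, gold$target, sep = "\r")
  common <- intersect(pk, gk)
  ps <- pred$sign[match(common, pk)]
  gs <- gold$sign[match(common, gk)]
  out <- list(TP = sum(ps == 1L & gs == 1L),
              TN = sum(ps == -1L & gs == -1L),
              FP = sum(ps == 1L & gs == -1L),
              FN = sum(ps == -1L & gs == 1L),
              n_pred_unmatched = length(pk) - length(common),
              n_gold_unrecovered = length(gk) - length(common))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Sign confusion: TP=%d TN=%d FP=%d FN=%d (unmatched pred %d, unrecovered gold %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$n_pred_unmatched, x$n_gold_unrecovered))
  invisible(x)
}

#' Sign accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`: the fraction of direction-matched
#' edges whose activation/repression label agrees with the gold standard.
#'
#' @param counts A `confusion_counts` object (or list with the four fields).
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  denom <- counts$TP + counts$TN + counts$FP + counts$FN
  if (denom == 0) stop("no matched edges to score", call. = FALSE)
  (counts$TP + counts$TN) / denom
}

#' Log2 fold change of one gene between phenotype groups
#'
#' `log2(mean over tumor samples / mean over normal samples)`. Both group
#' means must be positive; no pseudocount is applied.
#'
#' @param expr Expression matrix.
#' @param labels [phenotype_labels()].
#' @param gene Gene id.
#' @return Scalar log2 fold change.
#' @export
log_fold_change <- function(expr, labels, gene) {
  y <- .aligned_labels(expr, labels)
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene, call. = FALSE)
  if (!any(y == 1L) || !any(y == 0L)) stop("both phenotype groups must be nonempty", call. = FALSE)
  mt <- mean(expr[gene, y == 1L])
  mn <- mean(expr[gene, y == 0L])
  if (mt <= 0 || mn <= 0) {
    stop("nonpositive group mean for gene ", gene,
         "; log fold change undefined", call. = FALSE)
  }
  log2(mt / mn)
}

#' Differential-expression screen (Wilcoxon + FDR)
#'
#' Per gene: two-sided Wilcoxon rank-sum test between tumor and normal
#' samples, Benjamini-Hochberg adjustment across all genes, and a direction
#' call: `up` when `logFC > lfc_min` and adjusted p < `alpha`, `down` when
#' `logFC < -lfc_min` and adjusted p < `alpha`, otherwise `none`.
#'
#' @param expr Expression matrix with positive group means (required by the
#'   log fold change).
#' @param labels [phenotype_labels()]; both groups need >= 2 samples.
#' @param lfc_min Absolute log2-fold-change threshold (default 1, i.e.
#'   twofold).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A data.frame with columns `gene`, `logFC`, `p`, `p_adj`,
#'   `direction`.
#' @export
deg_screen <- function(expr, labels, lfc_min = 1, alpha = 0.05) {
  expr <- expression_matrix(expr)
  y <- .aligned_labels(expr, labels)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("each phenotype group needs at least 2 samples", call. = FALSE)
  }
  tum <- y == 1L; nor <- y == 0L
  genes <- rownames(expr)
  p <- vapply(genes, function(g) {
    suppressWarnings(stats::wilcox.test(expr[g, tum], expr[g, nor],
                                        exact = FALSE)$p.value)
  }, 0)
  lfc <- vapply(genes, function(g) log_fold_change(expr, labels, g), 0)
  p_adj <- stats::p.adjust(p, method = "BH")
  direction <- rep("none", length(genes))
  direction[lfc > lfc_min & p_adj < alpha] <- "up"
  direction[lfc < -lfc_min & p_adj < alpha] <- "down"
  .log("deg_screen: %d up, %d down of %d genes (|logFC| > %.2g, FDR < %.2g)",
       sum(direction == "up"), sum(direction == "down"), length(genes),
       lfc_min, alpha)
  data.frame(gene = genes, logFC = lfc, p = p, p_adj = p_adj,
             direction = direction, row.names = NULL, stringsAsFactors = FALSE)
}
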