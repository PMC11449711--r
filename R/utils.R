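# Internal helpers shared across modules.

#' @keywords internal
.log <- function(..., verbose = getOption("cser.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[cser] ", sprintf(...))
}

# Deterministic substream seed for (unit i, draw j) under one master seed.
# Keeps the derived seed strictly below 2^31 - 1.
#' @keywords internal
.substream_seed <- function(master, i, j = 0L) {
  m <- as.numeric(master) %% 100000
  as.integer((m * 20011 + as.numeric(i) * 10007 + as.numeric(j)) %% 2147483647)
}

#' @keywords internal
.assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < min) stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

#' Validate and construct an expression matrix
#'
#' Canonical container for expression data: a numeric genes x samples matrix
#' with unique gene identifiers as row names and sample identifiers as column
#' names. All downstream functions assume this orientation.
#'
#' @param values Numeric matrix, genes in rows.
#' @param gene_ids Optional character vector of gene identifiers (defaults to
#'   existing row names).
#' @param sample_ids Optional character vector of sample identifiers.
#' @return A numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  n <- nrow(values); m <- ncol(values)
  if (n < 2L || m < 3L) {
    stop("expression matrix needs at least 2 genes and 3 samples", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("expression values must all be finite", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(n))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(m))
  gene_ids <- as.character(gene_ids); sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != n || length(sample_ids) != m) {
    stop("dimnames do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Construct phenotype labels
#'
#' Binary sample labels (0 = normal, 1 = tumor) used by the coexpression
#' screen and the differential-expression screen.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param label Integer vector of 0/1 labels, same length.
#' @return A data.frame with columns `sample_id` and `label`.
#' @export
phenotype_labels <- function(sample_ids, label) {
  sample_ids <- as.character(sample_ids)
  label <- as.integer(label)
  if (length(sample_ids) != length(label)) stop("lengths differ", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (any(!label %in% c(0L, 1L))) stop("labels must be 0 (normal) or 1 (tumor)", call. = FALSE)
  data.frame(sample_id = sample_ids, label = label, stringsAsFactors = FALSE)
}

# Match a label data.frame against an expression matrix; returns the 0/1
# vector aligned to the matrix columns.
#' @keywords internal
.aligned_labels <- function(expr, labels) {
  if (is.null(dim(labels)) && !is.null(names(labels))) {
    labels <- phenotype_labels(names(labels), labels)
  }
  idx <- match(colnames(expr), labels$sample_id)
  if (anyNA(idx)) {
    stop("labels missing for samples: ",
         paste(utils::head(colnames(expr)[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  labels$label[idx]
}
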