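# Readers and writers for the two on-disk formats: expression matrices and
# signed edge lists. Tab-separated, UTF-8, "." decimal throughout.

#' @keywords internal
.is_numeric_field <- function(x) {
  suppressWarnings(!is.na(as.numeric(x)))
}

#' Read an expression matrix
#'
#' Supports two tab-separated layouts: `genes_by_samples` (one header line of
#' sample ids; each body row is a gene id followed by numeric values) and
#' `samples_by_genes` (DREAM4 style: one header line of gene names; each body
#' row is one sample, either purely numeric or led by a sample id).
#' `orientation = "auto"` treats the header row as gene names when every body
#' field is numeric, and otherwise assumes a leading gene-id column.
#'
#' @param path Path to a TSV file.
#' @param orientation One of `"auto"`, `"genes_by_samples"`,
#'   `"samples_by_genes"`.
#' @return An [expression_matrix()] (genes x samples).
#' @export
read_expression <- function(path,
                            orientation = c("auto", "genes_by_samples",
                                            "samples_by_genes")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("expression file needs a header and body: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  width <- lengths(body)
  if (length(unique(width)) != 1L) {
    stop("ragged rows in expression file (row ",
         which(width != width[1L])[1L] + 1L, ")", call. = FALSE)
  }
  first_fields <- vapply(body, `[[`, "", 1L)
  body_all_numeric <- all(.is_numeric_field(first_fields))

  if (orientation == "auto") {
    # gene-name header when the body is purely numeric (DREAM4 layout) or
    # when the corner cell labels a sample-id column
    sample_corner <- tolower(header[1L]) %in% c("sample", "samples", "sample_id")
    orientation <- if (body_all_numeric || sample_corner) {
      "samples_by_genes"
    } else {
      "genes_by_samples"
    }
  }

  parse_numeric <- function(rows, drop_first, row_labels) {
    vals <- lapply(seq_along(rows), function(i) {
      f <- rows[[i]]
      if (drop_first) f <- f[-1L]
      v <- suppressWarnings(as.numeric(f))
      if (anyNA(v)) {
        j <- which(is.na(v))[1L]
        stop(sprintf("non-numeric value '%s' at data row %d, column %d",
                     f[j], i, j + as.integer(drop_first)), call. = FALSE)
      }
      v
    })
    matrix(unlist(vals), nrow = length(vals), byrow = TRUE,
           dimnames = list(row_labels, NULL))
  }

  if (orientation == "genes_by_samples") {
    gene_ids <- first_fields
    mat <- parse_numeric(body, drop_first = TRUE, row_labels = gene_ids)
    m <- ncol(mat)
    sample_ids <- if (length(header) == m + 1L) header[-1L] else if (length(header) == m) header else
      stop("header width does not match body", call. = FALSE)
    out <- expression_matrix(mat, gene_ids, sample_ids)
  } else {
    has_sample_col <- !body_all_numeric
    mat <- parse_numeric(body, drop_first = has_sample_col, row_labels = NULL)
    n <- ncol(mat)
    gene_ids <- if (has_sample_col && length(header) == n + 1L) header[-1L] else if (length(header) == n) header else
      stop("header width does not match body", call. = FALSE)
    sample_ids <- if (has_sample_col) first_fields else paste0("S", seq_len(nrow(mat)))
    out <- expression_matrix(t(mat), gene_ids, sample_ids)
  }
  .log("read_expression: %d genes x %d samples from %s (%s)",
       nrow(out), ncol(out), path, orientation)
  out
}

#' Write an expression matrix
#'
#' Writes either layout read by [read_expression()]; values keep full double
#' precision so a round trip is exact.
#'
#' @param expr An expression matrix (genes x samples).
#' @param path Output path.
#' @param orientation `"samples_by_genes"` (DREAM4 style, with a leading
#'   sample-id column) or `"genes_by_samples"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path,
                             orientation = c("samples_by_genes",
                                             "genes_by_samples")) {
  orientation <- match.arg(orientation)
  fmt <- function(v) sprintf("%.17g", v)
  if (orientation == "samples_by_genes") {
    header <- paste(c("sample", rownames(expr)), collapse = "\t")
    rows <- vapply(seq_len(ncol(expr)), function(j) {
      paste(c(colnames(expr)[j], fmt(expr[, j])), collapse = "\t")
    }, "")
  } else {
    header <- paste(c("gene", colnames(expr)), collapse = "\t")
    rows <- vapply(seq_len(nrow(expr)), function(i) {
      paste(c(rownames(expr)[i], fmt(expr[i, ])), collapse = "\t")
    }, "")
  }
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a signed directed edge list
#'
#' Rows are `regulator<TAB>target<TAB>value` where `value` is either a signed
#' weight or a DREAM4-style indicator in \{-1, 0, 1\}. Rows with value 0 mean
#' "no edge" and are dropped; self-loop rows are dropped with a warning. An
#' optional header line is detected by a non-numeric third column.
#'
#' @param path Path to a TSV file.
#' @return A [signed_network()].
#' @export
read_signed_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(signed_network())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("malformed edge row (fewer than 3 columns) at line ",
         which(lengths(fields) < 3L)[1L], call. = FALSE)
  }
  # header detection: third column not numeric
  if (!.is_numeric_field(fields[[1L]][3L])) fields <- fields[-1L]
  if (length(fields) == 0L) return(signed_network())
  reg <- vapply(fields, `[[`, "", 1L)
  tgt <- vapply(fields, `[[`, "", 2L)
  val <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(val)) {
    stop("malformed edge row (non-numeric value) at body line ",
         which(is.na(val))[1L], call. = FALSE)
  }
  loops <- reg == tgt
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped", call. = FALSE)
  }
  keep <- !loops & val != 0
  signed_network(data.frame(regulator = reg[keep], target = tgt[keep],
                            weight = val[keep], stringsAsFactors = FALSE),
                 nodes = sort(unique(c(reg[!loops], tgt[!loops]))))
}

#' Write a signed directed edge list
#'
#' TSV with columns `regulator, target, weight, sign`, rows ordered
#' lexicographically by regulator then target, so output is deterministic and
#' [read_signed_network()] recovers the edge set and signs exactly.
#'
#' @param net A [signed_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signed_network <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  header <- "regulator\ttarget\tweight\tsign"
  if (nrow(net) == 0L) {
    writeLines(header, path, useBytes = TRUE)
    return(invisible(path))
  }
  ord <- order(net$regulator, net$target)
  rows <- sprintf("%s\t%s\t%.17g\t%d",
                  net$regulator[ord], net$target[ord],
                  net$weight[ord], net$sign[ord])
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read phenotype labels
#'
#' Two-column TSV `sample_id<TAB>label` with 0 = normal, 1 = tumor; an
#' optional header is detected by a non-numeric second column.
#'
#' @param path Path to a TSV file.
#' @return A [phenotype_labels()] data.frame.
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (!.is_numeric_field(tab[1L, 2L])) tab <- tab[-1L, , drop = FALSE]
  phenotype_labels(tab[[1L]], as.integer(as.numeric(tab[[2L]])))
}
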