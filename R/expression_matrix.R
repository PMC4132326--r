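#' Expression matrix container
#'
#' An `ExpressionMatrix` is a thin S3 wrapper around a numeric matrix with
#' genes in rows and samples in columns. Gene and sample identifiers are
#' unique character vectors carried as dimnames; missing cells are `NA`.
#'
#' @param values numeric matrix, rows = genes, columns = samples.
#' @param gene_ids character vector of unique gene identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match row count", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match column count", call. = FALSE)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(is.infinite(values)))
    stop("non-finite (infinite) expression values", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d missing cells)\n",
              length(x$gene_ids), length(x$sample_ids), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from delimited text
#'
#' Expects row 1 to hold sample identifiers, column 1 gene identifiers, and a
#' numeric body. Cells equal to `missing_token` become `NA`; any other
#' non-numeric cell is a parse error.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param missing_token string standing for a missing value (default `"NA"`).
#' @return An [expression_matrix()].
#' @export
load_matrix <- function(path, dialect = c("tsv", "csv"), missing_token = "NA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed header: need a gene-id column plus at least one sample column",
         call. = FALSE)
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  body[body == missing_token] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- !is.na(body) & is.na(num)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                 gene_ids[i[1]], sample_ids[i[2]], body[i[1], i[2]]),
         call. = FALSE)
  }
  rownames(num) <- gene_ids
  colnames(num) <- sample_ids
  expression_matrix(num, gene_ids, sample_ids)
}

#' Write an expression matrix as delimited text
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param missing_token token written for `NA` cells.
#' @export
write_matrix <- function(m, path, dialect = c("tsv", "csv"), missing_token = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- data.frame(gene_id = m$gene_ids,
                    format(m$values, digits = 15, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", m$sample_ids)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Reports dimensions, missing-cell count and warnings; in particular a
#' low-sample warning when fewer than `min_samples` sample conditions are
#' present, since pairwise curve fitting needs a large sample series.
#'
#' @param m an [expression_matrix()].
#' @param min_samples minimum advisable number of samples (default 20).
#' @return A list of class `ValidationReport` with `n_genes`, `n_samples`,
#'   `n_missing` and `warnings`.
#' @export
validate_matrix <- function(m, min_samples = 20) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  warnings <- character(0)
  n_samples <- length(m$sample_ids)
  if (n_samples < min_samples)
    warnings <- c(warnings, sprintf(
      "low sample count: %d samples < %d; pairwise curve fits need a large sample series",
      n_samples, min_samples))
  n_const <- sum(apply(m$values, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) == 0 || stats::var(r) == 0 || !is.finite(stats::var(r))
  }))
  if (n_const > 0)
    warnings <- c(warnings, sprintf("%d constant (zero-variance) gene row(s)", n_const))
  structure(list(n_genes = length(m$gene_ids), n_samples = n_samples,
                 n_missing = sum(is.na(m$values)), warnings = warnings),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat(sprintf("ValidationReport: %d genes, %d samples, %d missing\n",
              x$n_genes, x$n_samples, x$n_missing))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}

#' Standardize an expression matrix gene-wise
#'
#' Centres every gene row to mean 0 and scales to unit sample variance
#' (computed on non-missing cells). Constant rows cannot be standardized and
#' are excluded. PCOP geometry is not scale invariant, so all pairwise
#' analysis runs on standardized rows; the operation is idempotent.
#'
#' @param m an [expression_matrix()].
#' @return A standardized [expression_matrix()] (possibly with fewer genes);
#'   excluded gene ids are attached as attribute `"excluded"`.
#' @export
standardize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mu <- rowMeans(m$values, na.rm = TRUE)
  sdv <- apply(m$values, 1, stats::sd, na.rm = TRUE)
  ok <- is.finite(sdv) & sdv > 0
  if (!any(ok)) stop("no analysable genes: all rows are constant", call. = FALSE)
  z <- (m$values[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
  out <- expression_matrix(z, m$gene_ids[ok], m$sample_ids)
  attr(out, "excluded") <- m$gene_ids[!ok]
  out
}
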