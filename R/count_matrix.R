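#' Construct a validated count matrix
#'
#' A `count_matrix` is an integer gene-by-sample expression matrix with
#' unique gene identifiers as rownames and unique sample identifiers as
#' colnames. It is the container every other stage of the pipeline consumes:
#' feature selection, negative-binomial parameter estimation, simulation and
#' transformation all operate on it.
#'
#' @param counts numeric matrix, genes in rows, samples in columns. Entries
#'   must be non-negative and exactly integral (abundance estimates with
#'   fractional values are rejected, since the downstream model is a count
#'   model).
#' @param gene_ids optional character vector of row identifiers; defaults to
#'   existing rownames.
#' @param sample_ids optional character vector of column identifiers;
#'   defaults to existing colnames.
#' @return an integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length != number of rows")
  if (length(sample_ids) != ncol(counts)) stop("sample_ids length != number of columns")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyNA(counts)) stop("missing values in counts")
  if (any(counts < 0)) stop("negative count")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("non-integral counts: values must be exact integers")
  }
  storage.mode(counts) <- "double" # keeps values > .Machine$integer.max safe
  counts <- round(counts)
  dimnames(counts) <- list(gene_ids, sample_ids)
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat("total counts:", format(sum(x), big.mark = ","), "\n")
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Supported formats: delimited text (csv/tsv, autodetected from the
#' extension or forced via `format`) and xlsx (first sheet; requires the
#' readxl package). The first column holds gene identifiers and the header
#' row sample identifiers.
#'
#' @param path file path.
#' @param format one of "auto", "csv", "tsv", "xlsx".
#' @return a [count_matrix()].
#' @export
load_count_matrix <- function(path, format = c("auto", "csv", "tsv", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", xlsx = "xlsx", "tsv")
  }
  if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package")
    }
    df <- as.data.frame(readxl::read_excel(path, col_names = TRUE))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2) stop("expected gene-id column plus at least one sample")
  gene_ids <- as.character(df[[1]])
  mat <- df[, -1, drop = FALSE]
  numeric_ok <- vapply(mat, is.numeric, logical(1))
  if (!all(numeric_ok)) stop("non-numeric cells in count columns: ",
                             paste(names(mat)[!numeric_ok], collapse = ", "))
  mat <- as.matrix(mat)
  count_matrix(mat, gene_ids = gene_ids, sample_ids = colnames(mat))
}

#' Write a count matrix as tab-separated text
#'
#' The inverse of [load_count_matrix()]: first column `gene_id`, one column
#' per sample. Round-trips losslessly.
#'
#' @param x a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
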