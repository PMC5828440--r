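#' Moment-based sample skewness
#'
#' g1 = m3 / m2^(3/2), with m_j the j-th central sample moment using
#' divisor n (the common default of scientific moment functions). The
#' bias-corrected variant G1 = g1 * sqrt(n(n-1))/(n-2) is available via
#' `bias_correct`.
#'
#' @param v numeric vector, length >= 3, nonzero variance.
#' @param bias_correct apply the small-sample correction, default FALSE.
#' @return scalar skewness.
#' @export
sample_skewness <- function(v, bias_correct = FALSE) {
  n <- length(v)
  if (n < 3) stop("need at least 3 values")
  d <- v - mean(v)
  m2 <- mean(d^2)
  if (m2 == 0) stop("constant vector: skewness undefined")
  g1 <- mean(d^3) / m2^1.5
  if (bias_correct) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Moment-based sample excess kurtosis
#'
#' g2 = m4 / m2^2 - 3 (normal = 0; negative values are platykurtic). The
#' bias-corrected variant is available via `bias_correct`.
#'
#' @param v numeric vector, length >= 4, nonzero variance.
#' @param bias_correct apply the small-sample correction, default FALSE.
#' @return scalar excess kurtosis.
#' @export
sample_excess_kurtosis <- function(v, bias_correct = FALSE) {
  n <- length(v)
  if (n < 4) stop("need at least 4 values")
  d <- v - mean(v)
  m2 <- mean(d^2)
  if (m2 == 0) stop("constant vector: kurtosis undefined")
  g2 <- mean(d^4) / m2^2 - 3
  if (bias_correct) {
    ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else {
    g2
  }
}

#' Aggregate per-gene normality over a batch of transformed datasets
#'
#' For every dataset, skewness and excess kurtosis are computed per gene
#' across the samples and averaged over genes (genes with zero variance in
#' a dataset are excluded from that dataset's average, with a count kept).
#' The reported mean is the mean over datasets and the SE is the standard
#' deviation of the dataset-level values divided by sqrt(n_datasets), so it
#' reflects Monte-Carlo replicate variation.
#'
#' @param batch list of `transformed_matrix` (or plain matrices), one per
#'   replicate dataset, all the same shape.
#' @param design optional `sim_design` supplying category / K metadata.
#' @param transform_tag optional tag override for plain-matrix input.
#' @return list of class `normality_summary` with mean/SE skewness and
#'   excess kurtosis, `n_datasets`, and `n_zero_variance_excluded`.
#' @export
summarize_normality <- function(batch, design = NULL, transform_tag = NULL) {
  if (!length(batch)) stop("empty batch")
  get_vals <- function(x) if (inherits(x, "transformed_matrix")) x$values else unclass(x)
  tag <- transform_tag %||%
    (if (inherits(batch[[1]], "transformed_matrix")) batch[[1]]$transform_tag else "unknown")
  excluded <- 0L
  per_dataset <- vapply(batch, function(x) {
    m <- get_vals(x)
    vars <- apply(m, 1L, stats::var)
    ok <- vars > 0
    excluded <<- excluded + sum(!ok)
    sk <- apply(m[ok, , drop = FALSE], 1L, sample_skewness)
    kt <- apply(m[ok, , drop = FALSE], 1L, sample_excess_kurtosis)
    c(sk = mean(sk), kt = mean(kt))
  }, c(sk = 0, kt = 0))
  nd <- length(batch)
  if (nd == 1) warning("single dataset: standard errors undefined, reported as NA")
  se <- function(x) if (nd > 1) stats::sd(x) / sqrt(nd) else NA_real_
  structure(list(transform_tag = tag,
                 category = design$category %||% NA_character_,
                 K = design$K %||% NA_integer_,
                 mean_skewness = mean(per_dataset["sk", ]),
                 se_skewness = se(per_dataset["sk", ]),
                 mean_kurtosis = mean(per_dataset["kt", ]),
                 se_kurtosis = se(per_dataset["kt", ]),
                 n_datasets = nd,
                 n_zero_variance_excluded = excluded),
            class = "normality_summary")
}

#' @export
print.normality_summary <- function(x, ...) {
  cat(sprintf("normality [%s%s]: skewness %.3f (%.3f), excess kurtosis %.3f (%.3f), %d datasets\n",
              x$transform_tag,
              if (!is.na(x$category)) paste0(", ", x$category, " K=", x$K) else "",
              x$mean_skewness, x$se_skewness, x$mean_kurtosis, x$se_kurtosis,
              x$n_datasets))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
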