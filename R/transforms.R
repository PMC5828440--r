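#' @noRd
new_transformed_matrix <- function(values, source, tag, params = list()) {
  dimnames(values) <- dimnames(source)
  structure(list(values = values, transform_tag = tag,
                 transform_params = params),
            class = "transformed_matrix")
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("transformed_matrix [%s]: %d x %d\n", x$transform_tag,
              nrow(x$values), ncol(x$values)))
  if (length(x$transform_params)) {
    cat("  params:", paste(names(x$transform_params), unlist(x$transform_params),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Naive transformation (identity)
#'
#' Counts pass through unchanged; the reference point every other
#' transformation is compared against.
#'
#' @param matrix a [count_matrix()] or numeric matrix.
#' @return a `transformed_matrix` with tag "naive".
#' @export
transform_naive <- function(matrix) {
  m <- unclass(matrix)
  new_transformed_matrix(m + 0.0, m, "naive")
}

#' Log2 transformation with pseudocount
#'
#' Elementwise log2(x + pseudocount). The pseudocount (default 1) keeps
#' zeros finite; it is recorded in `transform_params`.
#'
#' @param matrix a [count_matrix()] or numeric matrix.
#' @param pseudocount added before the log, default 1.
#' @return a `transformed_matrix` with tag "log2".
#' @export
transform_log2 <- function(matrix, pseudocount = 1) {
  m <- unclass(matrix)
  new_transformed_matrix(log2(m + pseudocount), m, "log2",
                         list(pseudocount = pseudocount))
}

#' Blom rank-based inverse normal scores
#'
#' Maps a vector to approximate standard-normal quantiles:
#' qnorm((r_i - 3/8) / (n + 1/4)) where r_i is the average rank of value i
#' (ties share the mean rank). For odd n the middle rank maps to exactly 0.
#'
#' @param values numeric vector, length >= 2, not all equal.
#' @return numeric vector of normal scores.
#' @export
blom_scores <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (length(unique(values)) == 1) stop("constant vector: ranks undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Blom transformation of a count matrix
#'
#' Applies [blom_scores()] along one axis. The default, `per_sample`,
#' rank-normalizes each sample's gene profile (each column of the
#' gene-by-sample matrix); this leaves per-gene distributions free to be
#' skewed, which is what makes downstream per-gene skewness informative.
#' `per_gene` rank-normalizes each gene across samples, forcing per-gene
#' skewness to ~0 on tie-free data.
#'
#' @param matrix a [count_matrix()] or numeric matrix (genes x samples).
#' @param axis "per_sample" (default) or "per_gene".
#' @return a `transformed_matrix` with tag "blom".
#' @export
transform_blom <- function(matrix, axis = c("per_sample", "per_gene")) {
  axis <- match.arg(axis)
  m <- unclass(matrix)
  out <- if (axis == "per_sample") {
    apply(m, 2L, blom_scores)
  } else {
    t(apply(m, 1L, blom_scores))
  }
  new_transformed_matrix(out, m, "blom", list(axis = axis))
}

#' Pooled NB dispersion estimate (method of moments)
#'
#' Estimates a single over-dispersion alpha solving Var = mu + alpha * mu^2
#' across genes: per gene, alpha_g = (s_g^2 - m_g) / m_g^2; the pooled
#' estimate is the median over genes with positive alpha_g (under-dispersed
#' genes carry no information about alpha). If every gene is
#' under-dispersed the floor 1e-8 is returned, which makes the downstream
#' VST collapse to the Poisson form 2*sqrt(x).
#'
#' @param matrix a [count_matrix()] or numeric matrix (genes x samples).
#' @param floor smallest returned alpha, default 1e-8.
#' @return positive scalar alpha.
#' @export
estimate_common_dispersion <- function(matrix, floor = 1e-8) {
  m <- unclass(matrix)
  means <- rowMeans(m)
  vars <- apply(m, 1L, stats::var)
  keep <- means > 0
  if (sum(keep) < 2) stop("need >= 2 genes with positive mean")
  if (all(vars[keep] == 0)) stop("degenerate matrix: all genes constant")
  alpha_g <- (vars[keep] - means[keep]) / means[keep]^2
  alpha_g <- alpha_g[alpha_g > 0]
  if (!length(alpha_g)) return(floor)
  max(stats::median(alpha_g), floor)
}

#' Variance stabilizing transformation for NB counts
#'
#' With pooled dispersion alpha (estimated from the matrix itself via
#' [estimate_common_dispersion()]), applies the closed-form integral of
#' 1 / sqrt(mu + alpha mu^2):
#'   u(x) = (2 / sqrt(alpha)) * asinh(sqrt(alpha * x)).
#' As alpha -> 0 this tends to the Poisson-stabilizing 2*sqrt(x). The
#' estimated alpha is recorded in `transform_params`.
#'
#' @param matrix a [count_matrix()] or numeric matrix.
#' @param alpha optional fixed dispersion; estimated from the data when NULL.
#' @return a `transformed_matrix` with tag "vst".
#' @export
transform_vst <- function(matrix, alpha = NULL) {
  m <- unclass(matrix)
  if (is.null(alpha)) alpha <- estimate_common_dispersion(m)
  if (alpha <= 0) stop("alpha must be positive")
  out <- (2 / sqrt(alpha)) * asinh(sqrt(alpha * m))
  new_transformed_matrix(out, m, "vst", list(alpha = alpha))
}

#' Apply a transformation by name
#'
#' CLI-facing dispatcher over the four study transformations.
#'
#' @param matrix a [count_matrix()] or numeric matrix.
#' @param name one of "naive", "log", "blom", "vst" ("log2" accepted as an
#'   alias of "log").
#' @param ... passed to the specific transform.
#' @return a `transformed_matrix`.
#' @export
apply_transform <- function(matrix, name, ...) {
  switch(match.arg(name, c("naive", "log", "log2", "blom", "vst")),
         naive = transform_naive(matrix),
         log = ,
         log2 = transform_log2(matrix, ...),
         blom = transform_blom(matrix, ...),
         vst = transform_vst(matrix, ...))
}
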