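#' Negative binomial maximum likelihood fit for one gene
#'
#' Intercept-only NB fit under the size parameterization
#' Var = mu + mu^2 / k. With no covariates the likelihood separates: the MLE
#' of the mean is the sample mean, and the dispersion k is found by
#' one-dimensional maximization of the profile log-likelihood over log k
#' (golden-section/Brent search on log k in [-10, 18.4], tolerance 1e-8).
#' When the sample variance does not exceed the sample mean the NB MLE for k
#' diverges (Poisson limit); such fits are returned at the dispersion cap
#' with `boundary = TRUE`.
#'
#' @param counts_g integer vector of counts for a single gene (length >= 2,
#'   at least one positive entry).
#' @param k_cap dispersion cap for (near-)Poisson genes, default 1e8.
#' @return list of class `nb_params`: `mu`, `k`, `loglik`, `converged`,
#'   `boundary`.
#' @export
fit_nb_mle <- function(counts_g, k_cap = 1e8) {
  counts_g <- as.numeric(counts_g)
  if (length(counts_g) < 2) stop("need at least 2 observations")
  if (anyNA(counts_g) || any(counts_g < 0)) stop("counts must be non-negative")
  if (all(counts_g == 0)) stop("all-zero vector: NB mean undefined at 0")
  mu <- mean(counts_g)
  v <- stats::var(counts_g)
  nll <- function(logk) -sum(stats::dnbinom(counts_g, size = exp(logk),
                                            mu = mu, log = TRUE))
  if (v <= mu) {
    # under-dispersed: profile likelihood increases monotonically in k
    k <- k_cap
    return(structure(list(mu = mu, k = k, loglik = -nll(log(k)),
                          converged = TRUE, boundary = TRUE),
                     class = "nb_params"))
  }
  opt <- stats::optimize(nll, interval = c(-10, 18.4), tol = 1e-8)
  k <- exp(opt$minimum)
  boundary <- k >= exp(18.4) * (1 - 1e-6)
  if (boundary) k <- k_cap
  structure(list(mu = mu, k = min(k, k_cap), loglik = -opt$objective,
                 converged = TRUE, boundary = boundary),
            class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat(sprintf("nb_params: mu = %.4g, k = %.4g%s\n", x$mu, x$k,
              if (x$boundary) " (boundary: near-Poisson)" else ""))
  invisible(x)
}

#' NB log-likelihood at given parameters (helper for checks)
#'
#' @param counts_g integer vector.
#' @param mu,k NB mean and size.
#' @return scalar log-likelihood.
#' @export
nb_loglik <- function(counts_g, mu, k) {
  sum(stats::dnbinom(as.numeric(counts_g), size = k, mu = mu, log = TRUE))
}

#' Fit NB parameters for every gene of a panel
#'
#' Applies [fit_nb_mle()] row by row. All-zero genes cannot be fit; they are
#' dropped with a warning naming them, so the returned panel parameters may
#' be shorter than the requested panel.
#'
#' @param matrix a [count_matrix()].
#' @param panel a `gene_panel` or character vector of gene ids; default all
#'   genes of `matrix`.
#' @return object of class `nb_panel_params`: named list `params`
#'   (gene id -> `nb_params`), plus `mu` and `k` numeric vectors for
#'   convenience and `selection_mode` metadata.
#' @export
estimate_panel_params <- function(matrix, panel = NULL) {
  if (is.null(panel)) panel <- rownames(matrix)
  ids <- if (inherits(panel, "gene_panel")) panel$gene_ids else as.character(panel)
  sub <- unclass(subset_panel(matrix, ids))
  all_zero <- rowSums(sub) == 0
  if (any(all_zero)) {
    warning("excluding all-zero genes: ",
            paste(ids[all_zero], collapse = ", "))
    ids <- ids[!all_zero]
    sub <- sub[!all_zero, , drop = FALSE]
  }
  fits <- lapply(seq_along(ids), function(i) {
    tryCatch(fit_nb_mle(sub[i, ]),
             error = function(e) stop("gene ", ids[i], ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  names(fits) <- ids
  structure(list(params = fits,
                 mu = vapply(fits, `[[`, numeric(1), "mu"),
                 k = vapply(fits, `[[`, numeric(1), "k"),
                 selection_mode = if (inherits(panel, "gene_panel"))
                   panel$selection_mode else "all"),
            class = "nb_panel_params")
}

#' @export
print.nb_panel_params <- function(x, ...) {
  cat(sprintf("nb_panel_params: %d genes (%s)\n", length(x$params),
              x$selection_mode))
  cat(sprintf("  mu range [%.3g, %.3g]; k range [%.3g, %.3g]; %d boundary fits\n",
              min(x$mu), max(x$mu), min(x$k), max(x$k),
              sum(vapply(x$params, `[[`, logical(1), "boundary"))))
  invisible(x)
}

#' Serialize / deserialize panel parameters
#'
#' Tab-separated table keyed by gene id with columns mu, k, boundary.
#'
#' @param x an `nb_panel_params`.
#' @param path file path.
#' @return `path` (write) or `nb_panel_params` (read).
#' @export
write_panel_params <- function(x, path) {
  df <- data.frame(gene_id = names(x$params), mu = x$mu, k = x$k,
                   boundary = vapply(x$params, `[[`, logical(1), "boundary"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_params
#' @export
read_panel_params <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(mu = df$mu[i], k = df$k[i], loglik = NA_real_,
                   converged = TRUE, boundary = df$boundary[i]),
              class = "nb_params")
  })
  names(fits) <- df$gene_id
  structure(list(params = fits, mu = stats::setNames(df$mu, df$gene_id),
                 k = stats::setNames(df$k, df$gene_id),
                 selection_mode = "deserialized"),
            class = "nb_panel_params")
}
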