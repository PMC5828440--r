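#' Gaussian mixture model fitting by EM
#'
#' Fits a K-component Gaussian mixture to samples-in-rows data with one of
#' four diagonal/spherical covariance families (full covariance is
#' deliberately excluded: with p ~ 100 features and n ~ 55 samples it is
#' unidentifiable). Initialization is kmeans++-style seeding with
#' `n_init` restarts; the fit with the best final log-likelihood is kept.
#' EM stops when the log-likelihood improves by less than `tol` or after
#' `max_iter` iterations; a floor of `var_floor` is applied to every fitted
#' variance. The per-iteration log-likelihood sequence is non-decreasing
#' (up to numerical tolerance) and is returned for inspection.
#'
#' Covariance families (mixture-modeling "volume/shape" analogues):
#' \describe{
#'   \item{spherical_equal}{one scalar variance shared by all clusters}
#'   \item{spherical_varying}{one scalar variance per cluster}
#'   \item{diag_equal}{one variance per feature, shared by all clusters}
#'   \item{diag_varying}{one variance per feature per cluster}
#' }
#'
#' @param data numeric matrix, samples x features.
#' @param K number of mixture components, 1 <= K <= n.
#' @param cov_model one of the four family names above.
#' @param seed integer seed controlling the restarts.
#' @param n_init number of kmeans++ restarts, default 10.
#' @param max_iter EM iteration cap, default 500.
#' @param tol absolute log-likelihood convergence tolerance, default 1e-6.
#' @param var_floor variance floor, default 1e-6.
#' @return list of class `fitted_mixture`: `K`, `cov_model`, `weights`,
#'   `means` (K x p), `variances` (K x p, expanded to per-cluster-per-feature
#'   regardless of family), `loglik`, `loglik_trace`, `n_params`,
#'   `responsibilities` (n x K), `labels`.
#' @export
gmm_fit <- function(data, K, cov_model = c("diag_varying", "diag_equal",
                                           "spherical_varying", "spherical_equal"),
                    seed = 1, n_init = 10, max_iter = 500, tol = 1e-6,
                    var_floor = 1e-6) {
  cov_model <- match.arg(cov_model)
  X <- as.matrix(data)
  if (!all(is.finite(X))) stop("data must be finite")
  n <- nrow(X); p <- ncol(X)
  if (K > n) stop("K (", K, ") exceeds number of samples (", n, ")")
  if (K == 1) {
    fit <- gmm_k1_fit(X, cov_model, var_floor)
    return(fit)
  }
  best <- NULL
  errors <- character(0)
  for (init in seq_len(n_init)) {
    fit <- tryCatch(
      gmm_em_once(X, K, cov_model, seed = seed * 1000L + init,
                  max_iter = max_iter, tol = tol, var_floor = var_floor),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("all ", n_init, " EM restarts failed: ",
         paste(unique(errors), collapse = "; "))
  }
  best
}

#' Closed-form K = 1 fit (no latent structure)
#' @noRd
gmm_k1_fit <- function(X, cov_model, var_floor) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  centered <- sweep(X, 2L, mu)
  per_feature <- colMeans(centered^2)
  v <- switch(cov_model,
              diag_varying = ,
              diag_equal = per_feature,
              spherical_varying = ,
              spherical_equal = rep(mean(per_feature), p))
  v <- pmax(v, var_floor)
  ll <- sum(stats::dnorm(X, mean = matrix(mu, n, p, byrow = TRUE),
                         sd = matrix(sqrt(v), n, p, byrow = TRUE), log = TRUE))
  structure(list(K = 1L, cov_model = cov_model, weights = 1,
                 means = matrix(mu, 1L, p),
                 variances = matrix(v, 1L, p),
                 loglik = ll, loglik_trace = ll,
                 n_params = gmm_n_params(1L, p, cov_model),
                 responsibilities = matrix(1, n, 1L),
                 labels = rep(1L, n)),
            class = "fitted_mixture")
}

#' kmeans++ center seeding
#' @noRd
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1], ])^2)
  for (c in seq_len(K - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[c + 1L] <- sample.int(n, 1L, prob = probs)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[c + 1L], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' Per-cluster diagonal-Gaussian log density matrix (n x K)
#' @noRd
gmm_logdens <- function(X, means, variances) {
  n <- nrow(X); K <- nrow(means)
  ld <- matrix(0, n, K)
  for (c in seq_len(K)) {
    v <- variances[c, ]
    centered <- sweep(X, 2L, means[c, ])
    ld[, c] <- -0.5 * (ncol(X) * log(2 * pi) + sum(log(v)) +
                         colSums(t(centered^2) / v))
  }
  ld
}

#' One EM run from a kmeans++ start
#' @noRd
gmm_em_once <- function(X, K, cov_model, seed, max_iter, tol, var_floor) {
  n <- nrow(X); p <- ncol(X)
  R <- with_seed(seed, {
    centers <- kmeanspp_centers(X, K)
    d2 <- vapply(seq_len(K), function(c) rowSums(sweep(X, 2L, centers[c, ])^2),
                 numeric(n))
    hard <- max.col(-d2, ties.method = "first")
    R0 <- matrix(0, n, K)
    R0[cbind(seq_len(n), hard)] <- 1
    R0
  })
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # M-step
    n_c <- colSums(R)
    # a component holding fewer than ~2 effective samples pins its variance
    # to the floor and sends the likelihood to a spurious spike; treat it as
    # collapsed so the restart loop can try a different initialization
    if (any(n_c < 2)) stop("cluster collapse: effective size below 2")
    weights <- n_c / n
    means <- (t(R) %*% X) / n_c
    wss <- matrix(0, K, p) # weighted sums of squared deviations
    for (c in seq_len(K)) {
      centered <- sweep(X, 2L, means[c, ])
      wss[c, ] <- colSums(R[, c] * centered^2)
    }
    variances <- switch(cov_model,
      diag_varying = wss / n_c,
      diag_equal = matrix(colSums(wss) / n, K, p, byrow = TRUE),
      spherical_varying = matrix(rowSums(wss) / (n_c * p), K, p),
      spherical_equal = matrix(sum(wss) / (n * p), K, p))
    variances <- pmax(variances, var_floor)
    # E-step
    lw <- gmm_logdens(X, means, variances) +
      matrix(log(weights), n, K, byrow = TRUE)
    m <- apply(lw, 1L, max)
    lse <- m + log(rowSums(exp(lw - m)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    R <- exp(lw - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  labels <- max.col(R, ties.method = "first")
  structure(list(K = as.integer(K), cov_model = cov_model, weights = weights,
                 means = means, variances = variances,
                 loglik = ll, loglik_trace = loglik_trace,
                 n_params = gmm_n_params(K, p, cov_model),
                 responsibilities = R, labels = labels),
            class = "fitted_mixture")
}

#' Free-parameter count for a (K, family) pair
#' @noRd
gmm_n_params <- function(K, p, cov_model) {
  var_params <- switch(cov_model,
                       spherical_equal = 1L,
                       spherical_varying = K,
                       diag_equal = p,
                       diag_varying = K * p)
  as.integer(K * p + var_params + (K - 1L))
}

#' @export
print.fitted_mixture <- function(x, ...) {
  cat(sprintf("fitted_mixture: K = %d, %s, loglik = %.2f, d = %d\n",
              x$K, x$cov_model, x$loglik, x$n_params))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Bayesian Information Criterion of a fitted mixture
#'
#' Maximization convention: BIC = 2*loglik - d*log(n); larger is better.
#' (Many texts minimize the negation; the sign here matches the convention
#' of the standard mixture-clustering engines.)
#'
#' @param fit a `fitted_mixture`.
#' @param n number of observations the fit used.
#' @return scalar BIC.
#' @export
bic <- function(fit, n) {
  2 * fit$loglik - fit$n_params * log(n)
}

#' Select number of clusters and covariance family by BIC
#'
#' Fits every (K, family) pair over `K_range` x `models` and returns the
#' BIC-maximizing fit together with the full BIC table. Fits that fail
#' (e.g. persistent empty-cluster collapse) are recorded as NA in the table
#' and never selected. Deterministic given `seed`.
#'
#' @param data numeric matrix, samples x features.
#' @param K_range candidate cluster counts, default 1:5.
#' @param models candidate covariance families, default all four.
#' @param seed integer seed.
#' @param ... passed to [gmm_fit()] (e.g. `n_init`).
#' @return list of class `clustering_result`: `labels`, `chosen_K`,
#'   `chosen_model`, `bic_table` (data.frame K, model, bic), `fit`, `seed`.
#' @export
select_model <- function(data, K_range = 1:5,
                         models = c("spherical_equal", "spherical_varying",
                                    "diag_equal", "diag_varying"),
                         seed = 1, ...) {
  if (!length(K_range) || !length(models)) stop("empty K_range or models")
  grid <- expand.grid(K = K_range, model = models, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  bics <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(gmm_fit(data, K = grid$K[i], cov_model = grid$model[i],
                            seed = seed + i, ...),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      fits[[i]] <- fit
      bics[i] <- bic(fit, nrow(data))
    }
  }
  if (all(is.na(bics))) stop("all candidate fits failed")
  best <- which.max(bics)
  structure(list(labels = fits[[best]]$labels,
                 chosen_K = fits[[best]]$K,
                 chosen_model = fits[[best]]$cov_model,
                 bic_table = data.frame(K = grid$K, model = grid$model,
                                        bic = bics),
                 fit = fits[[best]],
                 seed = as.integer(seed)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: chosen K = %d (%s), BIC = %.2f\n",
              x$chosen_K, x$chosen_model,
              max(x$bic_table$bic, na.rm = TRUE)))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$chosen_K), collapse = " "), "\n")
  invisible(x)
}

#' Write a clustering result to disk
#'
#' Emits a tab-separated assignment file (sample_id, cluster) and a BIC
#' table file alongside it.
#'
#' @param result a `clustering_result`.
#' @param path assignment file path; the BIC table goes to
#'   `<path>.bic.tsv`.
#' @param sample_ids optional sample identifiers.
#' @return `path`, invisibly.
#' @export
write_clustering_result <- function(result, path, sample_ids = NULL) {
  ids <- sample_ids %||% sprintf("sample_%02d", seq_along(result$labels))
  utils::write.table(data.frame(sample_id = ids, cluster = result$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$bic_table, paste0(path, ".bic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
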