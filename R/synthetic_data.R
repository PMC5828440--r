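#' Surrogate ovarian-like count panel with known NB truth
#'
#' Generates a gene-by-sample count matrix whose per-gene negative binomial
#' parameters are drawn from log-normal distributions, together with the
#' generating truth. The defaults, ln mu ~ N(4, 2^2) and ln k ~ N(0, 1),
#' span zero-inflated low-count genes up to 1e4-scale counts with
#' gene-specific over-dispersion — a stand-in for a real bulk RNA-Seq tumor
#' panel, synthetic by construction and never a claim about any particular
#' dataset. It exists so every pipeline stage can be exercised and tested
#' without external files or network access.
#'
#' @param n_genes number of genes, default 100.
#' @param n_samples number of samples, default 55.
#' @param log_mu_location,log_mu_scale parameters of ln mu, defaults 4, 2.
#' @param log_k_location,log_k_scale parameters of ln k, defaults 0, 1.
#' @param seed integer seed.
#' @return list: `counts` (a [count_matrix()]) and `truth` (an
#'   `nb_panel_params` holding the generating mu and k per gene).
#' @export
generate_surrogate_panel <- function(n_genes = 100, n_samples = 55,
                                     log_mu_location = 4.0, log_mu_scale = 2.0,
                                     log_k_location = 0.0, log_k_scale = 1.0,
                                     seed = 1) {
  if (n_genes < 2 || n_samples < 2) stop("need at least 2 genes and 2 samples")
  if (log_mu_scale <= 0 || log_k_scale <= 0) stop("scales must be positive")
  with_seed(seed, {
    mu <- stats::rlnorm(n_genes, log_mu_location, log_mu_scale)
    k <- stats::rlnorm(n_genes, log_k_location, log_k_scale)
    ids <- sprintf("gene_%03d", seq_len(n_genes))
    counts <- matrix(
      stats::rnbinom(n_genes * n_samples, size = rep(k, times = n_samples),
                     mu = rep(mu, times = n_samples)),
      n_genes, n_samples,
      dimnames = list(ids, sprintf("sample_%02d", seq_len(n_samples))))
    fits <- lapply(seq_len(n_genes), function(g) {
      structure(list(mu = mu[g], k = k[g], loglik = NA_real_,
                     converged = TRUE, boundary = FALSE),
                class = "nb_params")
    })
    names(fits) <- ids
    list(counts = count_matrix(counts),
         truth = structure(list(params = fits,
                                mu = stats::setNames(mu, ids),
                                k = stats::setNames(k, ids),
                                selection_mode = "surrogate_truth"),
                           class = "nb_panel_params"))
  })
}

#' Load a supplementary count-matrix fixture
#'
#' Looks for the study's supplementary count tables (top-MAD panel or
#' random panel) in `fixture_dir`, accepting either the original xlsx files
#' or tab-separated conversions of them. These files are optional inputs:
#' when absent a clear error points at the surrogate generator instead, and
#' nothing in the package build or test suite depends on them.
#'
#' @param name "top_mad" (s001) or "random" (s002).
#' @param fixture_dir directory searched for the files; defaults to the
#'   package's extdata directory.
#' @return a [count_matrix()] of 100 genes x 55 samples.
#' @export
load_supplementary_fixture <- function(name = c("top_mad", "random"),
                                       fixture_dir = system.file("extdata",
                                                                 package = "nbclustsim")) {
  name <- match.arg(name)
  stem <- switch(name, top_mad = "pone.0191758.s001", random = "pone.0191758.s002")
  candidates <- file.path(fixture_dir, paste0(stem, c(".tsv", ".xlsx")))
  path <- candidates[file.exists(candidates)][1]
  if (is.na(path) || !length(path)) {
    stop("fixture missing: none of ", paste(basename(candidates), collapse = ", "),
         " found in ", fixture_dir,
         "; run with the surrogate generator instead (generate_surrogate_panel)")
  }
  mat <- load_count_matrix(path)
  if (nrow(mat) != 100 || ncol(mat) != 55) {
    stop("fixture ", basename(path), " has wrong shape: expected 100 x 55, got ",
         nrow(mat), " x ", ncol(mat))
  }
  mat
}
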