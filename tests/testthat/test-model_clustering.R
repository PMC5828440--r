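test_that("K = 1 fits are closed form", {
  X <- blob_data(10, 0, p = 4, seed = 1)
  f <- gmm_fit(X, 1, "diag_varying")
  expect_equal(f$means[1, ], colMeans(X))
  expect_equal(f$variances[1, ], colMeans(sweep(X, 2, colMeans(X))^2))
  # loglik equals sum of independent-Gaussian log densities
  ll <- sum(sapply(seq_len(ncol(X)), function(j)
    sum(dnorm(X[, j], mean(X[, j]), sqrt(mean((X[, j] - mean(X[, j]))^2)), log = TRUE))))
  expect_equal(f$loglik, ll)
  # spherical variant pools the variance
  fs <- gmm_fit(X, 1, "spherical_equal")
  expect_equal(unique(round(fs$variances[1, ], 12)),
               round(mean(colMeans(sweep(X, 2, colMeans(X))^2)), 12))
})

test_that("well-separated blobs are perfectly partitioned at K = 2", {
  X <- blob_data(c(15, 15), c(0, 20), p = 10, seed = 2)
  f <- gmm_fit(X, 2, "diag_varying", seed = 5)
  expect_true(all(f$responsibilities > 0.999 | f$responsibilities < 0.001))
  expect_equal(adjusted_rand_index(blob_labels(c(15, 15)), f$labels), 1)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  models <- c("diag_varying", "diag_equal", "spherical_varying", "spherical_equal")
  done <- 0L
  for (seed in 1:30) {
    X <- with_seed(seed, matrix(rnorm(40 * 6, sd = 1 + seed %% 3), 40, 6))
    # on pure noise a restart can collapse (a legitimate error); monotonicity
    # is asserted on fits that converge
    f <- tryCatch(gmm_fit(X, 2, models[1 + seed %% 4], seed = seed, n_init = 2),
                  error = function(e) NULL)
    if (is.null(f)) next
    done <- done + 1L
    expect_true(all(diff(f$loglik_trace) > -1e-6))
    if (done >= 10L) break
  }
  expect_gte(done, 10L)
})

test_that("responsibilities are row-stochastic and weights sum to one", {
  X <- blob_data(c(12, 12, 12), c(-6, 0, 6), p = 8, seed = 3)
  f <- gmm_fit(X, 3, "spherical_varying", seed = 1)
  expect_equal(rowSums(f$responsibilities), rep(1, 36))
  expect_equal(sum(f$weights), 1)
  expect_true(all(f$variances >= 1e-6))
})

test_that("free-parameter counts follow the family definitions", {
  X <- blob_data(c(10, 10), c(0, 20), p = 7, seed = 4)
  d_of <- function(K, model) gmm_fit(X, K, model, seed = 1, n_init = 2)$n_params
  p <- 7L
  expect_identical(d_of(1, "spherical_equal"), p + 1L)
  expect_identical(d_of(2, "diag_varying"), 4L * p + 1L)
  expect_identical(d_of(2, "diag_equal"), 2L * p + p + 1L)
  expect_identical(d_of(2, "spherical_varying"), 2L * p + 2L + 1L)
})

test_that("bic applies the maximization convention 2*ll - d*log(n)", {
  X <- blob_data(10, 0, p = 3, seed = 5)
  f <- gmm_fit(X, 1, "diag_varying")
  expect_equal(bic(f, 10), 2 * f$loglik - f$n_params * log(10))
  expect_gt(bic(f, 10), bic(f, 20)) # doubling n decreases BIC when d > 0
})

test_that("select_model recovers K on separable data and honors K_range", {
  X <- blob_data(c(18, 18, 19), c(0, 20, -20), p = 100, sd = 1, seed = 6)
  res <- select_model(X, seed = 2)
  expect_identical(res$chosen_K, 3L)
  expect_equal(adjusted_rand_index(blob_labels(c(18, 18, 19)), res$labels), 1)
  expect_identical(nrow(res$bic_table), 20L) # 5 K x 4 models
  best_row <- which.max(res$bic_table$bic)
  expect_identical(res$bic_table$K[best_row], res$chosen_K)

  forced <- select_model(X, K_range = 1, seed = 2)
  expect_identical(forced$chosen_K, 1L)
})

test_that("sample permutation permutes labels identically (up to relabeling)", {
  X <- blob_data(c(14, 14), c(0, 15), p = 12, seed = 7)
  perm <- with_seed(8, sample(nrow(X)))
  f1 <- gmm_fit(X, 2, "diag_varying", seed = 3)
  f2 <- gmm_fit(X[perm, ], 2, "diag_varying", seed = 3)
  expect_equal(adjusted_rand_index(f1$labels[perm], f2$labels), 1)
})

test_that("degenerate inputs error cleanly", {
  expect_error(gmm_fit(matrix(rnorm(6), 3, 2), 4), "exceeds")
  expect_error(gmm_fit(matrix(c(1, Inf, 2, 3), 2, 2), 1), "finite")
})

test_that("clustering results serialize to assignment + BIC files", {
  X <- blob_data(c(10, 10), c(0, 20), p = 5, seed = 9)
  res <- select_model(X, K_range = 1:3, seed = 1, n_init = 3)
  path <- tempfile(fileext = ".tsv")
  write_clustering_result(res, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(back$cluster, res$labels)
  bic_back <- read.table(paste0(path, ".bic.tsv"), header = TRUE, sep = "\t")
  expect_identical(nrow(bic_back), nrow(res$bic_table))
  unlink(c(path, paste0(path, ".bic.tsv")))
})
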