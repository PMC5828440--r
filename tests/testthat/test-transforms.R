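test_that("naive is the identity and idempotent", {
  cm <- toy_count_matrix()
  t1 <- transform_naive(cm)
  expect_equal(t1$values, unclass(cm), ignore_attr = TRUE)
  expect_identical(t1$transform_tag, "naive")
  expect_equal(transform_naive(t1$values)$values, t1$values)
})

test_that("log2 transform matches closed forms and is monotone", {
  cm <- count_matrix(matrix(c(0L, 3L, 7L, 15L), 2, 2))
  tv <- transform_log2(cm)$values
  expect_equal(sort(as.numeric(tv)), c(0, 2, 3, 4)) # log2(x + 1)
  x <- with_seed(2, sample(0:10000, 200))
  y <- log2(x + 1)
  expect_true(all(diff(y[order(x)]) > 0))
})

test_that("blom_scores match the normal-quantile formula", {
  # n = 3 distinct values
  expect_equal(blom_scores(c(10, 5, 20)),
               qnorm((c(2, 1, 3) - 0.375) / 3.25))
  expect_equal(blom_scores(c(10, 5, 20))[2], qnorm(0.625 / 3.25))
  expect_equal(unname(blom_scores(c(10, 5, 20))), c(0, -0.869, 0.869),
               tolerance = 1e-3)
  # n = 55: the unique middle rank maps to exactly zero ((28 - 3/8)/55.25 = 1/2)
  x <- with_seed(1, sample(1:55))
  expect_identical(blom_scores(x)[which(x == 28)], 0)
  expect_identical(blom_scores(1:55)[28], 0)
  # ties share average ranks
  expect_equal(blom_scores(c(1, 1, 2))[1:2],
               rep(qnorm((1.5 - 0.375) / 3.25), 2))
  expect_error(blom_scores(c(3, 3, 3)), "constant")
})

test_that("tie-free Blom scores are symmetric (zero skewness)", {
  s <- blom_scores(with_seed(4, runif(41)))
  expect_equal(sample_skewness(s), 0, tolerance = 1e-12)
  expect_lt(abs(mean(s)), 1e-10)
})

test_that("transform_blom respects the axis and preserves ranks", {
  m <- count_matrix(matrix(with_seed(5, sample(1:5000, 30 * 8)), 30, 8))
  per_sample <- transform_blom(m, "per_sample")$values
  per_gene <- transform_blom(m, "per_gene")$values
  expect_identical(dim(per_sample), dim(m))
  # per-sample: each column rank-normalized, mean ~ 0
  expect_true(all(abs(colMeans(per_sample)) < 1e-10))
  # per-gene: each row symmetric, skewness 0
  expect_true(all(abs(apply(per_gene, 1, sample_skewness)) < 1e-10))
  # rank preservation within the operating slice
  for (j in c(1, 4)) {
    expect_identical(order(per_sample[, j]), order(unclass(m)[, j]))
  }
  for (i in c(2, 9)) {
    expect_identical(order(per_gene[i, ]), order(unclass(m)[i, ]))
  }
})

test_that("estimate_common_dispersion recovers a shared alpha", {
  # NB with Var = mu + alpha mu^2 <=> size k = 1/alpha
  alpha <- 0.5
  mu <- with_seed(6, rlnorm(100, 4, 1.5))
  m <- with_seed(7, matrix(rnbinom(100 * 500, size = 1 / alpha,
                                   mu = rep(mu, 500)), 100, 500))
  a_hat <- estimate_common_dispersion(m)
  expect_lt(abs(a_hat - alpha) / alpha, 0.2)

  # Poisson data: at or near the floor
  pois <- with_seed(8, matrix(rpois(100 * 300, lambda = rep(mu, 300)), 100, 300))
  expect_lt(estimate_common_dispersion(pois), 0.01)

  # robustness: one over-dispersed gene among Poisson genes barely moves the median
  mixed <- rbind(pois, with_seed(9, rnbinom(300, size = 0.5, mu = 100)))
  expect_lt(estimate_common_dispersion(mixed), 0.01)
})

test_that("VST has the right closed form and Poisson limit", {
  x <- 0:1000
  vst_small <- (2 / sqrt(1e-9)) * asinh(sqrt(1e-9 * x))
  expect_true(all(abs(vst_small - 2 * sqrt(x)) < 1e-3))
  tm <- transform_vst(toy_count_matrix(), alpha = 0.7)
  expect_equal(tm$values[1, 1], (2 / sqrt(0.7)) * asinh(sqrt(0.7 * 5)))
  m0 <- count_matrix(matrix(c(0L, 2L, 5L, 0L), 2, 2))
  expect_true(all(transform_vst(m0, alpha = 2)$values[unclass(m0) == 0] == 0))
})

test_that("VST stabilizes per-gene variances relative to naive", {
  alpha <- 0.4
  mu <- with_seed(10, rlnorm(80, 4, 1.5))
  m <- with_seed(11, matrix(rnbinom(80 * 200, size = 1 / alpha,
                                    mu = rep(mu, 200)), 80, 200))
  cv <- function(x) sd(x) / mean(x)
  v_naive <- apply(m, 1, var)
  v_vst <- apply(transform_vst(m)$values, 1, var)
  expect_lt(cv(v_vst), cv(v_naive))
})

test_that("apply_transform dispatches by name and records params", {
  cm <- count_matrix(matrix(with_seed(12, sample(0:999, 40)), 8, 5))
  expect_identical(apply_transform(cm, "log")$transform_tag, "log2")
  expect_identical(apply_transform(cm, "vst")$transform_tag, "vst")
  expect_true(is.numeric(apply_transform(cm, "vst")$transform_params$alpha))
  expect_identical(apply_transform(cm, "blom", axis = "per_gene")$transform_params$axis,
                   "per_gene")
  expect_error(apply_transform(cm, "rlog"))
})
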