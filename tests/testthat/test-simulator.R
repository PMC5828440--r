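test_that("build_design reproduces the study size table", {
  expect_identical(build_design("TE", 2)$cluster_sizes, c(28L, 27L))
  expect_identical(build_design("TE", 3)$cluster_sizes, c(18L, 18L, 19L))
  expect_identical(build_design("TX", 2)$cluster_sizes, c(5L, 50L))
  expect_identical(build_design("TX", 3)$cluster_sizes, c(5L, 17L, 33L))
  d1 <- build_design("RE", 1)
  expect_identical(d1$cluster_sizes, 55L)
  expect_identical(d1$up_fractions, 0)
  expect_equal(sum(build_design("RX", 3)$cluster_sizes), 55)
  expect_equal(build_design("TE", 2)$shifts[["dmu1"]], exp(3.375))
  expect_equal(build_design("TE", 2)$shifts[["dmu2"]], exp(5.5))
  expect_error(build_design("TE", 4), "K must be")
})

test_that("up-gene assignment sizes, disjointness, and c2 sharing across K", {
  panel <- sprintf("g%03d", 1:100)
  d2 <- build_design("TE", 2, base_seed = 10)
  d3 <- build_design("TE", 3, base_seed = 10)
  up2 <- assign_up_genes(panel, d2)
  up3 <- assign_up_genes(panel, d3)
  expect_length(up2$c2, 10)
  expect_length(up3$c2, 10)
  expect_length(up3$c3, 20)
  expect_length(intersect(up3$c2, up3$c3), 0)
  # c2 is shared between K = 2 and K = 3 at the same base seed
  expect_setequal(up2$c2, up3$c2)
  expect_identical(assign_up_genes(panel, build_design("TE", 1)), list(c1 = character(0)))
})

test_that("effect shifts are multiplicative on the right clusters", {
  panel <- c("up2", "up3", "plain")
  fits <- structure(list(
    params = setNames(lapply(1:3, function(i)
      structure(list(mu = 10, k = 1, loglik = NA, converged = TRUE,
                     boundary = FALSE), class = "nb_params")), panel),
    mu = setNames(rep(10, 3), panel), k = setNames(rep(1, 3), panel),
    selection_mode = "manual"), class = "nb_panel_params")
  d <- build_design("TE", 3)
  up <- list(c1 = character(0), c2 = "up2", c3 = "up3")
  shifted <- apply_effect_shifts(fits, d, up)
  # baseline cluster untouched
  expect_equal(unname(shifted$c1$mu), rep(10, 3))
  # c2 up gene: mu * e^3.375 ~ 292.9, k * 1.01
  expect_equal(shifted$c2$mu[["up2"]], 10 * exp(3.375))
  expect_equal(shifted$c2$k[["up2"]], 1.01)
  # c3 up gene: mu * e^5.5, k * 1.03
  expect_equal(shifted$c3$mu[["up3"]], 10 * exp(5.5))
  expect_equal(shifted$c3$k[["up3"]], 1.03)
  # non-up gene identical everywhere
  for (c in 1:3) expect_equal(shifted[[c]]$mu[["plain"]], 10)
  # K = 1: identity
  d1 <- build_design("TE", 1)
  s1 <- apply_effect_shifts(fits, d1, list(c1 = character(0)))
  expect_equal(s1$c1$mu, fits$mu)
  expect_equal(s1$c1$k, fits$k)
})

test_that("simulate_dataset has the right shape, labels, and determinism", {
  sp <- generate_surrogate_panel(seed = 4)
  d <- build_design("TE", 3, base_seed = 20)
  up <- assign_up_genes(names(sp$truth$params), d)
  ds1 <- simulate_dataset(sp$truth, d, up, seed = 21)
  ds2 <- simulate_dataset(sp$truth, d, up, seed = 21)
  expect_identical(dim(ds1$counts), c(100L, 55L))
  expect_identical(unclass(ds1$counts), unclass(ds2$counts))
  expect_identical(tabulate(ds1$true_labels), d$cluster_sizes)
  ds3 <- simulate_dataset(sp$truth, d, up, seed = 22)
  expect_false(identical(unclass(ds1$counts), unclass(ds3$counts)))
})

test_that("simulated per-gene means match the generating NB means (K = 1)", {
  sp <- generate_surrogate_panel(n_genes = 40, seed = 6)
  d <- build_design("TE", 1, n_datasets = 200, base_seed = 100)
  batch <- simulate_batch(sp$truth, d)
  expect_length(batch, 200)
  # pool the 200 x 55 draws per gene; empirical mean within 3 MC SEs
  pooled <- do.call(cbind, lapply(batch, function(x) unclass(x$counts)))
  mu <- sp$truth$mu
  k <- sp$truth$k
  mc_se <- sqrt((mu + mu^2 / k) / ncol(pooled))
  within <- abs(rowMeans(pooled) - mu) <= 3 * mc_se
  expect_gte(mean(within), 0.95)
})

test_that("over-dispersion survives simulation for low-k genes", {
  sp <- generate_surrogate_panel(n_genes = 60, n_samples = 200, seed = 9)
  m <- unclass(sp$counts)
  lowk <- sp$truth$k < 1e3 & sp$truth$mu > 5
  vm <- apply(m, 1, var) / rowMeans(m)
  expect_gt(mean(vm[lowk] > 1), 0.9)
})

test_that("K = 1 batches are bit-identical across balance categories", {
  sp <- generate_surrogate_panel(seed = 14)
  bTE <- simulate_batch(sp$truth, build_design("TE", 1, n_datasets = 3, base_seed = 50))
  bTX <- simulate_batch(sp$truth, build_design("TX", 1, n_datasets = 3, base_seed = 50))
  for (i in 1:3) {
    expect_identical(unclass(bTE[[i]]$counts), unclass(bTX[[i]]$counts))
  }
})

test_that("replicate seeds produce distinct matrices", {
  sp <- generate_surrogate_panel(n_genes = 20, seed = 3)
  batch <- simulate_batch(sp$truth, build_design("RE", 2, n_datasets = 5, base_seed = 7))
  mats <- lapply(batch, function(x) unclass(x$counts))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(identical(mats[[i]], mats[[j]]))
  }
})
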