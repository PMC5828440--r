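#' Build one simulation design
#'
#' The study crosses four parent categories with K in 1..3 clusters over
#' N = 55 samples. Categories encode gene-panel choice and cluster balance:
#' TE / TX use the top-MAD panel with equal / extremely-unequal clusters,
#' RE / RX the random-filtered panel likewise. Cluster sizes follow the
#' study layout: equal designs use 28/27 (K = 2) and 18/18/19 (K = 3);
#' unequal designs use 5/50 and 5/17/33. Effect-size shifts applied to
#' up-expressed genes are Delta-mu1 = exp(3.375), Delta-mu2 = exp(5.5),
#' Delta-k1 = 1.01, Delta-k2 = 1.03. Cluster c1 is always the unshifted
#' baseline; 10% of genes are up-expressed in c2 and a further 20% in c3.
#'
#' @param category one of "TE", "RE", "TX", "RX".
#' @param K number of clusters, 1, 2 or 3.
#' @param n_datasets Monte-Carlo replicates (study default 100).
#' @param base_seed integer; replicate d uses seed base_seed + d - 1, and
#'   up-gene assignment uses base_seed - 1 so it is shared across K.
#' @param shift_mode "multiplicative" (default: mu <- mu * Delta-mu,
#'   k <- k * Delta-k, fold-change semantics) or "additive".
#' @return list of class `sim_design`.
#' @export
build_design <- function(category = c("TE", "RE", "TX", "RX"), K,
                         n_datasets = 100, base_seed = 1,
                         shift_mode = c("multiplicative", "additive")) {
  category <- match.arg(category)
  shift_mode <- match.arg(shift_mode)
  if (!K %in% 1:3) stop("K must be 1, 2 or 3")
  equal <- category %in% c("TE", "RE")
  cluster_sizes <- if (equal) {
    switch(K, `1` = 55L, `2` = c(28L, 27L), `3` = c(18L, 18L, 19L))
  } else {
    switch(K, `1` = 55L, `2` = c(5L, 50L), `3` = c(5L, 17L, 33L))
  }
  up_fractions <- switch(K, `1` = 0, `2` = c(0, 0.10), `3` = c(0, 0.10, 0.20))
  structure(list(category = category, K = as.integer(K),
                 cluster_sizes = cluster_sizes,
                 up_fractions = up_fractions,
                 shifts = c(dmu1 = exp(3.375), dmu2 = exp(5.5),
                            dk1 = 1.01, dk2 = 1.03),
                 shift_mode = shift_mode,
                 n_datasets = as.integer(n_datasets),
                 base_seed = as.integer(base_seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("sim_design %s K=%d: sizes [%s], up fractions [%s], %d datasets, base seed %d\n",
              x$category, x$K, paste(x$cluster_sizes, collapse = ", "),
              paste(x$up_fractions, collapse = ", "), x$n_datasets, x$base_seed))
  invisible(x)
}

#' Assign up-expressed gene sets per cluster
#'
#' Draws disjoint random gene sets for the shifted clusters. The c2 set is
#' drawn first from seed base_seed - 1, so the same 10% of genes is
#' up-expressed in c2 whether K = 2 or K = 3 (the c3 set is drawn next from
#' the remaining pool under the same stream).
#'
#' @param panel a `gene_panel` or character vector of gene ids.
#' @param design a `sim_design`.
#' @param seed optional override; defaults to design$base_seed - 1.
#' @return list of character vectors, one per cluster (c1 always empty).
#' @export
assign_up_genes <- function(panel, design, seed = design$base_seed - 1L) {
  ids <- if (inherits(panel, "gene_panel")) panel$gene_ids else as.character(panel)
  G <- length(ids)
  counts <- round(design$up_fractions * G)
  if (any(abs(design$up_fractions * G - counts) > 1e-9)) {
    stop("up fractions do not yield integer gene counts for panel size ", G)
  }
  if (sum(counts) > G) stop("requested up-gene sets exceed panel size")
  with_seed(seed, {
    sets <- vector("list", design$K)
    pool <- ids
    for (c in seq_len(design$K)) {
      if (counts[c] == 0) {
        sets[[c]] <- character(0)
      } else {
        sets[[c]] <- sample(pool, counts[c], replace = FALSE)
        pool <- setdiff(pool, sets[[c]])
      }
    }
    names(sets) <- paste0("c", seq_len(design$K))
    sets
  })
}

#' Apply effect-size shifts to panel parameters, per cluster
#'
#' Cluster c1 keeps the estimated parameters. For an up-expressed gene in
#' c2, (Delta-mu1, Delta-k1) applies; in c3, (Delta-mu2, Delta-k2). The
#' default mode multiplies mu and k by the shifts (fold-change semantics,
#' natural for "up-expressed" genes given the exp() form of the mean
#' shifts); an additive mode is available for comparison.
#'
#' @param params an `nb_panel_params`.
#' @param design a `sim_design`.
#' @param up_genes output of [assign_up_genes()].
#' @return list of K matrices-of-parameters: each element has `mu` and `k`
#'   named vectors over panel genes.
#' @export
apply_effect_shifts <- function(params, design, up_genes) {
  genes <- names(params$params)
  per_cluster <- vector("list", design$K)
  shift_pairs <- list(c(NA, NA),
                      c(design$shifts[["dmu1"]], design$shifts[["dk1"]]),
                      c(design$shifts[["dmu2"]], design$shifts[["dk2"]]))
  for (c in seq_len(design$K)) {
    mu <- params$mu[genes]
    k <- params$k[genes]
    if (c >= 2 && length(up_genes[[c]])) {
      idx <- genes %in% up_genes[[c]]
      dmu <- shift_pairs[[c]][1]
      dk <- shift_pairs[[c]][2]
      if (design$shift_mode == "multiplicative") {
        mu[idx] <- mu[idx] * dmu
        k[idx] <- k[idx] * dk
      } else {
        mu[idx] <- mu[idx] + dmu
        k[idx] <- k[idx] + dk
      }
    }
    per_cluster[[c]] <- list(mu = mu, k = k)
  }
  names(per_cluster) <- paste0("c", seq_len(design$K))
  per_cluster
}

#' Simulate one clustered count dataset
#'
#' Every entry x_gi is an independent draw from NB(mu_g(c_i), k_g(c_i))
#' where c_i is sample i's cluster. Samples are laid out in label-blocked
#' column order (cluster 1 first); downstream clustering is order-invariant
#' and blocked order keeps the ground truth trivial to track.
#'
#' @param params an `nb_panel_params`.
#' @param design a `sim_design`.
#' @param up_genes output of [assign_up_genes()].
#' @param seed integer seed for this replicate.
#' @return list of class `sim_dataset`: `counts` ([count_matrix()]),
#'   `true_labels` (integer per sample), `up_genes`, `seed`.
#' @export
simulate_dataset <- function(params, design, up_genes, seed) {
  cluster_params <- apply_effect_shifts(params, design, up_genes)
  genes <- names(params$params)
  G <- length(genes)
  labels <- rep(seq_len(design$K), times = design$cluster_sizes)
  N <- length(labels)
  counts <- with_seed(seed, {
    m <- matrix(0, G, N)
    for (c in seq_len(design$K)) {
      cols <- which(labels == c)
      n_c <- length(cols)
      mu <- cluster_params[[c]]$mu
      k <- cluster_params[[c]]$k
      # rnbinom recycles per gene: draw gene-major block
      m[, cols] <- matrix(
        stats::rnbinom(G * n_c, size = rep(k, times = n_c),
                       mu = rep(mu, times = n_c)),
        G, n_c)
    }
    m
  })
  rownames(counts) <- genes
  colnames(counts) <- sprintf("sample_%02d", seq_len(N))
  structure(list(counts = count_matrix(counts),
                 true_labels = labels,
                 up_genes = up_genes,
                 seed = as.integer(seed)),
            class = "sim_dataset")
}

#' Simulate a batch of replicate datasets
#'
#' Replicate d uses seed `base_seed + d - 1`; the up-gene assignment is
#' drawn once from `base_seed - 1` and shared by all replicates (and by
#' designs with different K sharing the base seed).
#'
#' @param params an `nb_panel_params`.
#' @param design a `sim_design`.
#' @param panel optional panel restricting which genes are simulated;
#'   defaults to all genes in `params`.
#' @return list of `sim_dataset`, length `design$n_datasets`.
#' @export
simulate_batch <- function(params, design, panel = names(params$params)) {
  if (design$n_datasets < 1) stop("n_datasets must be >= 1")
  up_genes <- assign_up_genes(panel, design)
  lapply(seq_len(design$n_datasets), function(d) {
    simulate_dataset(params, design, up_genes,
                     seed = design$base_seed + d - 1L)
  })
}
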