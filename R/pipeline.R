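#' Build a study configuration
#'
#' Collects every knob of the simulation study in one validated object.
#' The defaults reproduce the full study grid: four parent categories
#' (TE, RE, TX, RX), K in 1..3, four transformations, 100 replicate
#' datasets per scenario — 48 scenario-transform combinations in total.
#'
#' @param source either "surrogate" (default; the study runs on a
#'   [generate_surrogate_panel()] matrix) or a named list
#'   `list(top_mad = <path-or-matrix>, random = <path-or-matrix>)` of real
#'   count inputs.
#' @param categories subset of c("TE","RE","TX","RX").
#' @param K_set subset of 1:3.
#' @param transforms subset of c("naive","log","blom","vst").
#' @param n_datasets replicates per scenario, study default 100.
#' @param seed master integer seed; all per-scenario seeds derive from it.
#' @param blom_axis axis for the Blom transform, default "per_sample".
#' @param K_range candidate cluster counts for selection, default 1:5.
#' @param models candidate covariance families, default all four.
#' @param n_init EM restarts per fit, default 10.
#' @param panel_size genes per panel, default 100.
#' @param surrogate_args extra arguments to [generate_surrogate_panel()].
#' @return list of class `study_config`.
#' @export
study_config <- function(source = "surrogate",
                         categories = c("TE", "RE", "TX", "RX"),
                         K_set = 1:3,
                         transforms = c("naive", "log", "blom", "vst"),
                         n_datasets = 100, seed = 1,
                         blom_axis = "per_sample",
                         K_range = 1:5,
                         models = c("spherical_equal", "spherical_varying",
                                    "diag_equal", "diag_varying"),
                         n_init = 10, panel_size = 100,
                         surrogate_args = list()) {
  categories <- match.arg(categories, several.ok = TRUE)
  transforms <- match.arg(transforms,
                          c("naive", "log", "blom", "vst"), several.ok = TRUE)
  if (!length(K_set) || !all(K_set %in% 1:3)) stop("K_set must be within 1:3")
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  structure(list(source = source, categories = categories,
                 K_set = as.integer(sort(K_set)), transforms = transforms,
                 n_datasets = as.integer(n_datasets), seed = as.integer(seed),
                 blom_axis = blom_axis, K_range = K_range, models = models,
                 n_init = n_init, panel_size = as.integer(panel_size),
                 surrogate_args = surrogate_args),
            class = "study_config")
}

#' Resolve the source matrices for the two panel families
#' @noRd
resolve_source <- function(config) {
  if (identical(config$source, "surrogate")) {
    args <- utils::modifyList(list(seed = config$seed * 101L),
                              config$surrogate_args)
    base <- do.call(generate_surrogate_panel, args)$counts
    return(list(matrix = base))
  }
  get_mat <- function(x) if (inherits(x, "count_matrix")) x else load_count_matrix(x)
  list(top_mad = get_mat(config$source$top_mad),
       random = get_mat(config$source$random))
}

#' Panel parameters for one category under a config
#' @noRd
category_params <- function(config, src, category) {
  if (!is.null(src$matrix)) {
    # surrogate: one base matrix, panels selected from it like on real data
    if (category %in% c("TE", "TX")) {
      panel <- select_top_mad(src$matrix, min(config$panel_size, nrow(src$matrix)))
      estimate_panel_params(src$matrix, panel)
    } else {
      panel <- select_random_filtered(src$matrix,
                                      min(config$panel_size, floor(nrow(src$matrix) / 2)),
                                      seed = config$seed * 7L)
      estimate_panel_params(src$matrix, panel)
    }
  } else {
    # fixture mode: the shipped matrices ARE the panels
    mat <- if (category %in% c("TE", "TX")) src$top_mad else src$random
    estimate_panel_params(mat)
  }
}

#' Deterministic per-scenario base seed
#' @noRd
scenario_seed <- function(master, category, K) {
  # panel family (not balance) determines the stream so TE/TX share draws at
  # K = 1, mirroring the identical K = 1 summaries across balance settings
  fam <- if (category %in% c("TE", "TX")) 1L else 2L
  as.integer(master * 10000L + fam * 100L + K * 10L)
}

#' Run the simulation study
#'
#' For each (category, K): estimates NB parameters from the category's
#' source panel, simulates `n_datasets` count datasets, applies each
#' configured transformation, summarizes normality, and (for K >= 2)
#' clusters every transformed dataset — samples as observations, genes as
#' features — with BIC model selection and scores the recovered partition
#' against the simulated truth. K = 1 scenarios carry no partition metrics
#' (there is no multi-cluster truth to compare against).
#'
#' @param config a [study_config()].
#' @param progress print per-scenario progress lines, default FALSE.
#' @return list of class `study_result`: `summaries` (one per
#'   scenario-transform), `config`.
#' @export
run_simulation_study <- function(config, progress = FALSE) {
  src <- resolve_source(config)
  summaries <- list()
  for (category in config$categories) {
    params <- category_params(config, src, category)
    for (K in config$K_set) {
      base_seed <- scenario_seed(config$seed, category, K)
      design <- build_design(category, K, n_datasets = config$n_datasets,
                             base_seed = base_seed)
      batch <- simulate_batch(params, design)
      for (tf in config$transforms) {
        t0 <- Sys.time()
        transformed <- lapply(batch, function(d) {
          if (tf == "blom") apply_transform(d$counts, tf, axis = config$blom_axis)
          else apply_transform(d$counts, tf)
        })
        norm_sum <- summarize_normality(transformed, design)
        clust <- NULL
        if (K >= 2) {
          scores <- vector("list", length(batch))
          failures <- 0L
          for (d in seq_along(batch)) {
            res <- tryCatch(
              select_model(t(transformed[[d]]$values),
                           K_range = config$K_range, models = config$models,
                           seed = base_seed + 1000L + d, n_init = config$n_init),
              error = function(e) NULL)
            if (is.null(res)) { failures <- failures + 1L; next }
            scores[[d]] <- c(unlist(evaluate_partition(batch[[d]]$true_labels,
                                                       res$labels)),
                             chosen_K = res$chosen_K)
          }
          sc <- do.call(rbind, scores)
          nd <- nrow(sc)
          clust <- list(
            mean = colMeans(sc[, c("ari", "cer", "ci"), drop = FALSE]),
            se = apply(sc[, c("ari", "cer", "ci"), drop = FALSE], 2L,
                       function(x) if (nd > 1) stats::sd(x) / sqrt(nd) else NA_real_),
            mean_chosen_K = mean(sc[, "chosen_K"]),
            n_scored = nd, n_failures = failures)
        }
        summaries[[paste(category, K, tf, sep = "_")]] <-
          structure(list(category = category, K = K, transform = tf,
                         normality = norm_sum, clustering = clust,
                         base_seed = base_seed,
                         n_datasets = config$n_datasets),
                    class = "scenario_summary")
        if (progress) {
          message(sprintf("[%s K=%d %s] done in %.1fs", category, K, tf,
                          as.numeric(difftime(Sys.time(), t0, units = "secs"))))
        }
      }
    }
  }
  structure(list(summaries = summaries, config = config),
            class = "study_result")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("scenario %s K=%d %s: skew %.3f, kurt %.3f",
              x$category, x$K, x$transform,
              x$normality$mean_skewness, x$normality$mean_kurtosis))
  if (!is.null(x$clustering)) {
    cat(sprintf("; ARI %.3f, CER %.3f, CI %.3f (mean chosen K %.2f)",
                x$clustering$mean["ari"], x$clustering$mean["cer"],
                x$clustering$mean["ci"], x$clustering$mean_chosen_K))
  }
  cat("\n")
  invisible(x)
}

#' Cluster a real (or surrogate) count matrix after each transformation
#'
#' The real-data path of the study: each configured transformation is
#' applied to the matrix and the samples are clustered with the number of
#' clusters unknown (BIC selection over `K_range`). A failure under one
#' transformation does not abort the others.
#'
#' @param matrix a [count_matrix()] (genes x samples).
#' @param transforms transformation names, default all four.
#' @param seed integer seed.
#' @param K_range candidate cluster counts, default 1:5.
#' @param blom_axis Blom axis, default "per_sample".
#' @param ... passed to [select_model()].
#' @return named list per transform: a `clustering_result`, or a condition
#'   object for transforms that failed.
#' @export
cluster_real_data <- function(matrix, transforms = c("naive", "log", "blom", "vst"),
                              seed = 1, K_range = 1:5,
                              blom_axis = "per_sample", ...) {
  if (ncol(matrix) < 2) stop("need at least 2 samples")
  out <- list()
  for (i in seq_along(transforms)) {
    tf <- transforms[i]
    out[[tf]] <- tryCatch({
      tm <- if (tf == "blom") apply_transform(matrix, tf, axis = blom_axis)
            else apply_transform(matrix, tf)
      select_model(t(tm$values), K_range = K_range, seed = seed + i, ...)
    }, error = function(e) e)
  }
  out
}

#' Write study report tables
#'
#' Emits the long-format normality table (transform, category, K, mean and
#' SE of skewness and kurtosis), the clustering-metrics table (transform,
#' category, K, metric, mean, se), and a machine-readable run manifest
#' recording the configuration and seeds so any number in the tables can be
#' regenerated.
#'
#' @param result a `study_result` from [run_simulation_study()].
#' @param outdir output directory, created if needed.
#' @return character vector of written file paths, invisibly.
#' @export
write_report <- function(result, outdir) {
  if (!length(result$summaries)) stop("no summaries to report")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  norm_rows <- lapply(result$summaries, function(s) {
    data.frame(transform = s$transform, category = s$category, K = s$K,
               mean_sk = s$normality$mean_skewness,
               se_sk = s$normality$se_skewness,
               mean_kt = s$normality$mean_kurtosis,
               se_kt = s$normality$se_kurtosis,
               n_datasets = s$normality$n_datasets)
  })
  norm_path <- file.path(outdir, "normality_table.tsv")
  utils::write.table(do.call(rbind, norm_rows), norm_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  metric_rows <- list()
  for (s in result$summaries) {
    if (is.null(s$clustering)) next
    for (m in c("ari", "cer", "ci")) {
      metric_rows[[length(metric_rows) + 1L]] <-
        data.frame(transform = s$transform, category = s$category, K = s$K,
                   metric = m, mean = unname(s$clustering$mean[m]),
                   se = unname(s$clustering$se[m]),
                   n_scored = s$clustering$n_scored,
                   n_failures = s$clustering$n_failures)
    }
  }
  metrics_path <- file.path(outdir, "clustering_metrics.tsv")
  if (length(metric_rows)) {
    utils::write.table(do.call(rbind, metric_rows), metrics_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(
      data.frame(transform = character(0), category = character(0),
                 K = integer(0), metric = character(0), mean = numeric(0),
                 se = numeric(0), n_scored = integer(0),
                 n_failures = integer(0)),
      metrics_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- result$config
  manifest <- c(
    paste0("package_version\t", as.character(utils::packageVersion("nbclustsim"))),
    paste0("r_version\t", R.version.string),
    paste0("seed\t", cfg$seed),
    paste0("source\t", if (identical(cfg$source, "surrogate")) "surrogate" else "fixtures"),
    paste0("categories\t", paste(cfg$categories, collapse = ",")),
    paste0("K_set\t", paste(cfg$K_set, collapse = ",")),
    paste0("transforms\t", paste(cfg$transforms, collapse = ",")),
    paste0("n_datasets\t", cfg$n_datasets),
    paste0("blom_axis\t", cfg$blom_axis),
    paste0("K_range\t", paste(cfg$K_range, collapse = ",")),
    paste0("models\t", paste(cfg$models, collapse = ",")),
    paste0("n_init\t", cfg$n_init),
    paste0("panel_size\t", cfg$panel_size))
  manifest_path <- file.path(outdir, "run_manifest.tsv")
  writeLines(manifest, manifest_path)
  invisible(c(norm_path, metrics_path, manifest_path))
}
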