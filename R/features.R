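#' Median absolute deviation of a numeric vector
#'
#' median(|x - median(x)|), scaled by the normal-consistency constant
#' (1.4826 by default, as in [stats::mad()]). Gene selection depends only on
#' MAD ranks, so the constant is cosmetic; it is exposed so that invariance
#' can be demonstrated.
#'
#' @param values numeric vector, length >= 1.
#' @param constant scaling constant, default 1.4826.
#' @return non-negative scalar.
#' @export
gene_mad <- function(values, constant = 1.4826) {
  if (length(values) < 1) stop("empty vector")
  stats::mad(values, constant = constant)
}

#' Gene panel constructor (internal)
#'
#' @noRd
new_gene_panel <- function(gene_ids, selection_mode, seed = NA_integer_) {
  structure(list(gene_ids = as.character(gene_ids),
                 selection_mode = selection_mode,
                 seed = seed),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d genes, mode = %s\n",
              length(x$gene_ids), x$selection_mode))
  invisible(x)
}

#' Per-gene MAD for a count matrix
#' @noRd
row_mads <- function(matrix, constant = 1.4826) {
  apply(unclass(matrix), 1L, gene_mad, constant = constant)
}

#' Select the top-m genes by median absolute deviation
#'
#' The standard "most variable genes" panel: genes ranked by MAD across
#' samples, largest first. Ties at the selection boundary are broken by
#' ascending gene id, making the panel deterministic and invariant to row
#' order.
#'
#' @param matrix a [count_matrix()].
#' @param m panel size, 1 <= m <= number of genes.
#' @param constant MAD scaling constant (does not affect selection).
#' @return a `gene_panel` with `selection_mode = "top_mad"`.
#' @export
select_top_mad <- function(matrix, m, constant = 1.4826) {
  G <- nrow(matrix)
  if (m < 1 || m > G) stop("m must be between 1 and the number of genes (", G, ")")
  mads <- row_mads(matrix, constant)
  ids <- rownames(matrix)
  ord <- order(-mads, ids) # descending MAD, ties by ascending id
  new_gene_panel(ids[ord][seq_len(m)], "top_mad")
}

#' Select a random gene panel after discarding the low-MAD half
#'
#' Removes the floor(G/2) genes with smallest MAD (boundary ties resolved by
#' gene id, mirroring the top-MAD rule), then draws m genes uniformly
#' without replacement from the surviving pool. Reproducible given `seed`.
#'
#' @param matrix a [count_matrix()].
#' @param m panel size.
#' @param seed integer seed for the random draw.
#' @return a `gene_panel` with `selection_mode = "random_filtered"`.
#' @export
select_random_filtered <- function(matrix, m, seed) {
  G <- nrow(matrix)
  mads <- row_mads(matrix)
  ids <- rownames(matrix)
  n_drop <- floor(G / 2)
  ord <- order(mads, ids) # ascending: first n_drop are removed
  pool <- sort(ids[ord][seq(n_drop + 1L, G)])
  if (length(pool) < m) {
    stop("insufficient genes after filtering: pool of ", length(pool),
         " cannot supply ", m)
  }
  chosen <- with_seed(seed, sample(pool, m, replace = FALSE))
  new_gene_panel(chosen, "random_filtered", seed = as.integer(seed))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never clobbers
#' the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Extract the sub-matrix for a gene panel
#'
#' @param matrix a [count_matrix()].
#' @param panel a `gene_panel` (or character vector of gene ids).
#' @return a [count_matrix()] restricted to the panel genes, in panel order.
#' @export
subset_panel <- function(matrix, panel) {
  ids <- if (inherits(panel, "gene_panel")) panel$gene_ids else as.character(panel)
  missing <- setdiff(ids, rownames(matrix))
  if (length(missing)) stop("panel genes absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  count_matrix(unclass(matrix)[ids, , drop = FALSE])
}
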