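#' @noRd
check_pair <- function(truth, estimate) {
  if (length(truth) != length(estimate)) stop("label vectors differ in length")
  if (length(truth) < 2) stop("need at least 2 samples")
  if (anyNA(truth) || anyNA(estimate)) stop("missing labels")
  list(truth = as.integer(factor(truth)),
       estimate = as.integer(factor(estimate)))
}

#' Rand index between two partitions
#'
#' Fraction of unordered sample pairs on which the two partitions agree: a
#' pair agrees if it is co-clustered in both partitions or separated in
#' both. Computed from the contingency table in O(size of table).
#'
#' @param truth,estimate label vectors of equal length.
#' @return scalar in [0, 1].
#' @export
rand_index <- function(truth, estimate) {
  pr <- check_pair(truth, estimate)
  n <- length(pr$truth)
  tab <- table(pr$truth, pr$estimate)
  sum_nij2 <- sum(choose(tab, 2))
  sum_a2 <- sum(choose(rowSums(tab), 2))
  sum_b2 <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # agreements = co-clustered in both + separated in both
  (total + 2 * sum_nij2 - sum_a2 - sum_b2) / total
}

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Chance-corrected pairwise agreement:
#' (Index - E[Index]) / (Max - E[Index]) over the pair-count contingency
#' table. 1 for identical partitions, ~0 for independent ones. In the
#' doubly-degenerate case (both partitions trivial so Max = E[Index]) the
#' value is 1 for identical partitions and 0 otherwise.
#'
#' @param truth,estimate label vectors of equal length.
#' @return scalar <= 1.
#' @export
adjusted_rand_index <- function(truth, estimate) {
  pr <- check_pair(truth, estimate)
  n <- length(pr$truth)
  tab <- table(pr$truth, pr$estimate)
  index <- sum(choose(tab, 2))
  sum_a2 <- sum(choose(rowSums(tab), 2))
  sum_b2 <- sum(choose(colSums(tab), 2))
  expected <- sum_a2 * sum_b2 / choose(n, 2)
  max_index <- (sum_a2 + sum_b2) / 2
  if (abs(max_index - expected) < .Machine$double.eps * max(1, max_index)) {
    return(if (identical(pr$truth, pr$estimate)) 1 else 0)
  }
  (index - expected) / (max_index - expected)
}

#' Clustering error rate
#'
#' Defined here as exactly 1 minus the (unadjusted) Rand index. Note that
#' other literature defines CER via permutation-minimized misclassification;
#' that quantity is available as [misclassification_rate()] to avoid
#' ambiguity.
#'
#' @param truth,estimate label vectors of equal length.
#' @return scalar in [0, 1].
#' @export
cer <- function(truth, estimate) {
  1 - rand_index(truth, estimate)
}

#' Permutation-minimized misclassification rate
#'
#' The smallest fraction of misassigned samples over all one-to-one
#' relabelings of the estimated clusters (enumerates label permutations;
#' intended for small cluster counts).
#'
#' @param truth,estimate label vectors of equal length.
#' @return scalar in [0, 1].
#' @export
misclassification_rate <- function(truth, estimate) {
  pr <- check_pair(truth, estimate)
  kt <- max(pr$truth); ke <- max(pr$estimate)
  k <- max(kt, ke)
  if (k > 8) stop("misclassification_rate enumerates permutations; k <= 8 only")
  perms <- permutations_of(k)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    mapped <- perms[i, ][pr$estimate]
    best <- min(best, mean(mapped != pr$truth))
  }
  best
}

#' All permutations of 1..k, one per row
#' @noRd
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Concordance index for partition recovery
#'
#' Pairwise co-membership AUC: over all combinations of one within-truth-
#' cluster sample pair and one between-truth-cluster sample pair, the
#' fraction where the estimated partition ranks them correctly
#' (co-clusters the within pair AND separates the between pair), with 0.5
#' credit when the estimate treats both pairs alike. Equals 1 for perfect
#' recovery and 0.5 for any uninformative (e.g. constant) estimate. NA when
#' the truth has a single cluster (no between pairs to rank).
#'
#' @param truth,estimate label vectors of equal length.
#' @return scalar in [0, 1], or NA for a single-cluster truth.
#' @export
concordance_index <- function(truth, estimate) {
  pr <- check_pair(truth, estimate)
  n <- length(pr$truth)
  idx <- utils::combn(n, 2)
  within_truth <- pr$truth[idx[1, ]] == pr$truth[idx[2, ]]
  co_est <- pr$estimate[idx[1, ]] == pr$estimate[idx[2, ]]
  n_within <- sum(within_truth)
  n_between <- sum(!within_truth)
  if (n_between == 0 || n_within == 0) return(NA_real_)
  # counts over the 2x2 (truth-pair type x estimate-co-membership) table
  w1 <- sum(co_est[within_truth])    # within pairs the estimate co-clusters
  w0 <- n_within - w1
  b1 <- sum(co_est[!within_truth])   # between pairs the estimate co-clusters
  b0 <- n_between - b1
  (w1 * b0 + 0.5 * (w1 * b1 + w0 * b0)) / (n_within * n_between)
}

#' All four partition scores at once
#'
#' @param truth,estimate label vectors of equal length.
#' @return named list: `rand`, `ari`, `cer`, `ci`.
#' @export
evaluate_partition <- function(truth, estimate) {
  r <- rand_index(truth, estimate)
  list(rand = r,
       ari = adjusted_rand_index(truth, estimate),
       cer = 1 - r,
       ci = concordance_index(truth, estimate))
}
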