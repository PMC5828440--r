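# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive (pair enumeration, direct
# moment sums) so it shares no code path with the package implementation.

# --- partition-metric oracles (O(n^2) pair enumeration) ---------------------

pair_counts_oracle <- function(truth, estimate) {
  n <- length(truth)
  n11 <- n00 <- n10 <- n01 <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ct <- truth[i] == truth[j]
      ce <- estimate[i] == estimate[j]
      if (ct && ce) n11 <- n11 + 1L
      else if (!ct && !ce) n00 <- n00 + 1L
      else if (ct && !ce) n10 <- n10 + 1L
      else n01 <- n01 + 1L
    }
  }
  c(n11 = n11, n00 = n00, n10 = n10, n01 = n01)
}

rand_oracle <- function(truth, estimate) {
  pc <- pair_counts_oracle(truth, estimate)
  (pc["n11"] + pc["n00"]) / sum(pc)
}

ari_oracle <- function(truth, estimate) {
  pc <- as.numeric(pair_counts_oracle(truth, estimate))
  n11 <- pc[1]; n00 <- pc[2]; n10 <- pc[3]; n01 <- pc[4]
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(if (n10 + n01 == 0) 1 else 0)
  2 * (n11 * n00 - n10 * n01) / den
}

ci_oracle <- function(truth, estimate) {
  n <- length(truth)
  within <- list(); between <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (truth[i] == truth[j]) within[[length(within) + 1]] <- c(i, j)
      else between[[length(between) + 1]] <- c(i, j)
    }
  }
  if (!length(within) || !length(between)) return(NA_real_)
  total <- 0
  for (w in within) {
    for (b in between) {
      cw <- estimate[w[1]] == estimate[w[2]]
      cb <- estimate[b[1]] == estimate[b[2]]
      if (cw && !cb) total <- total + 1
      else if (cw == cb) total <- total + 0.5
    }
  }
  total / (length(within) * length(between))
}

# all set partitions of n elements as label vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (v in seq_len(next_max + 1)) {
      recurse(c(labels, v), max(next_max, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# --- small fixtures ---------------------------------------------------------

toy_count_matrix <- function() {
  # rows engineered to have unscaled MADs 0, 1, 1, 3, 9
  m <- rbind(g_const = c(5, 5, 5, 5, 5),
             g_mad1a = c(1, 2, 3, 4, 5),
             g_mad1b = c(10, 11, 12, 13, 14),
             g_mad3  = c(0, 3, 6, 9, 12),
             g_mad9  = c(0, 9, 18, 27, 36))
  colnames(m) <- paste0("s", 1:5)
  count_matrix(m)
}

# well-separated Gaussian blobs, samples in rows
blob_data <- function(sizes, centers, p = 20, sd = 1, seed = 1) {
  with_seed(seed, {
    do.call(rbind, lapply(seq_along(sizes), function(c) {
      matrix(rnorm(sizes[c] * p, mean = centers[c], sd = sd), sizes[c], p)
    }))
  })
}

blob_labels <- function(sizes) rep(seq_along(sizes), times = sizes)
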