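# Shared fixtures, built in code at test time.

tmp_fasta <- function(..., file = tempfile(fileext = ".fasta")) {
  writeLines(c(...), file)
  file
}

random_dna <- function(n, len, probs = rep(0.25, 4), seed = NULL) {
  gen <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = ""
      )
    }, character(1))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Build a class_mean_profile by hand (M_pos/M_neg given per k).
manual_profile <- function(M_pos, M_neg, pseudocount = 0) {
  ks <- as.integer(names(M_pos))
  structure(
    list(
      k_range = ks, pseudocount = pseudocount, log_base = "natural",
      M_pos = M_pos, M_neg = M_neg, n_pos = 1L, n_neg = 1L
    ),
    class = "class_mean_profile"
  )
}

# Profile with M_pos = M_neg = uniform for k = 1..6 (every kmerscore is 0).
symmetric_profile <- function(k_range = 1:6) {
  u <- lapply(k_range, function(k) rep(1 / 4^k, 4^k))
  names(u) <- as.character(k_range)
  manual_profile(u, u)
}

# Brute-force k-mer frequency oracle: enumerate every window with substring.
brute_kmer_freq <- function(seq, k) {
  n <- nchar(seq)
  words <- vapply(seq_len(n - k + 1), function(i) substr(seq, i, i + k - 1),
    character(1)
  )
  counts <- table(factor(words, levels = all_kmers(k)))
  as.numeric(counts) / (n - k + 1)
}

# Rank-statistic (concordance) AUROC oracle.
rank_auroc <- function(scores, y) {
  y <- as.numeric(y)
  r <- rank(scores)
  np <- sum(y == 1)
  nn <- sum(y == 0)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

# Average-precision oracle for the step-wise PR area (no ties assumed).
ap_oracle <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  cum_tp <- cumsum(y)
  prec <- cum_tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

# Small, fast CNN configuration for unit tests (same stage arithmetic as the
# default: final feature maps of length 15).
quick_cnn <- function(epochs = 5L, seed = 1L, dropout_rate = 0.1, ...) {
  cnn_config(
    filters_per_layer = c(8L, 8L), kernel_sizes = c(7L, 13L),
    pool_sizes = c(2L, 2L), dense_units = 8L, dropout_rate = dropout_rate,
    epochs = epochs, seed = seed, ...
  )
}

# Tiny labeled datasets with a planted composition gap, for pipeline tests.
tiny_gap_data <- function(n_pos = 15, n_neg = 25, len = 60, seed = 7) {
  withr::with_seed(seed, {
    pos <- dataset(
      sprintf("P%03d", seq_len(n_pos)),
      random_dna(n_pos, len, probs = c(0.1, 0.4, 0.4, 0.1)),
      label = "positive",
      gene = sprintf("G%02d", rep(seq_len(ceiling(n_pos / 3)), each = 3)[seq_len(n_pos)])
    )
    neg <- dataset(
      sprintf("N%03d", seq_len(n_neg)),
      random_dna(n_neg, len, probs = c(0.4, 0.1, 0.1, 0.4)),
      label = "negative"
    )
    list(pos = pos, neg = neg)
  })
}
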