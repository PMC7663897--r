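BASES <- c("A", "C", "G", "T")

#' All k-mers in lexicographic order
#'
#' @param k Word length (>= 1).
#' @return Character vector of the 4^k words over `A < C < G < T`.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1)
  g <- do.call(expand.grid, c(rep(list(BASES), k), stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; lexicographic order needs the
  # last sequence position fastest, so paste columns in reverse.
  do.call(paste0, rev(as.list(g)))
}

# Encode a sequence as integers 0..3 (A,C,G,T).
seq_codes <- function(seq) {
  v <- match(strsplit(seq, "", fixed = TRUE)[[1L]], BASES) - 1L
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T}", call. = FALSE)
  v
}

# 1-based lexicographic index of each overlapping k-mer window.
window_indices <- function(codes, k) {
  n <- length(codes)
  m <- n - k + 1L
  idx <- integer(m)
  for (j in seq_len(k)) idx <- idx * 4L + codes[j:(m + j - 1L)]
  idx + 1L
}

#' Overlapping k-mer frequencies of a sequence
#'
#' Counts every length-`k` window of the sequence (with overlap) and divides
#' by the number of windows, `n - k + 1`. For example the 3-mers of `"AAAAC"`
#' occur with frequencies 2/3 (`AAA`) and 1/3 (`AAC`).
#'
#' @param x A sequence string over `{A,C,G,T}`, a single-row [dataset()], or a
#'   one-element subset thereof.
#' @param k Word length; requires `nchar(seq) >= k`.
#' @return Numeric vector of length 4^k, named by k-mer in lexicographic
#'   order, summing to 1.
#' @export
kmer_frequencies <- function(x, k) {
  seq <- as_sequence(x)
  n <- nchar(seq)
  if (n < k) {
    stop(
      "sequence", record_tag(x), " of length ", n,
      " is shorter than k = ", k,
      call. = FALSE
    )
  }
  idx <- window_indices(seq_codes(seq), k)
  counts <- tabulate(idx, nbins = 4L^k)
  stats::setNames(counts / (n - k + 1L), all_kmers(k))
}

as_sequence <- function(x) {
  if (inherits(x, "triplex_dataset") || is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single record", call. = FALSE)
    return(x$seq)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

record_tag <- function(x) {
  if ((inherits(x, "triplex_dataset") || is.data.frame(x)) && nrow(x) == 1L) {
    return(paste0(" '", x$id, "'"))
  }
  ""
}

#' Fit class-mean k-mer profiles
#'
#' Computes, for each `k` in `k_range`, the arithmetic mean k-mer frequency
#' vector of the positive records (`M_pos`) and of the negative records
#' (`M_neg`). These class means are the fitted state behind the kmerscore
#' feature: a sequence is scored by how much its composition resembles the
#' negative versus the positive class mean.
#'
#' To keep the log-ratio defined when a k-mer is absent from one class
#' (virtually certain for k = 6 on small training sets), each mean vector is
#' smoothed by adding `pseudocount` to every entry and renormalizing.
#'
#' The caller is responsible for passing training data only: fitting the
#' profile on sequences that are later scored as test data leaks class
#' information into the features.
#'
#' @param pos,neg Non-empty [dataset()]s of the positive and negative class.
#' @param k_range Integer vector of word lengths (default 1..6). Every
#'   sequence must be at least `max(k_range)` long.
#' @param pseudocount Positive smoothing constant (default 1e-6); 0 disables
#'   smoothing (the resulting profile may then be unusable for kmerscore).
#' @return A `class_mean_profile` with elements `k_range`, `pseudocount`,
#'   `log_base = "natural"`, `M_pos`, `M_neg` (lists indexed by `k`), and the
#'   class sizes.
#' @export
fit_class_means <- function(pos, neg, k_range = 1:6, pseudocount = 1e-6) {
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("both classes must be non-empty to fit class means", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  kmax <- max(k_range)
  short <- c(pos$id[nchar(pos$seq) < kmax], neg$id[nchar(neg$seq) < kmax])
  if (length(short) > 0L) {
    stop(
      "sequence(s) shorter than max(k_range) = ", kmax, ": ",
      paste(utils::head(short, 5), collapse = ", "),
      call. = FALSE
    )
  }
  mean_profile <- function(seqs, k) {
    m <- rep(0, 4L^k)
    for (s in seqs) {
      n <- nchar(s)
      idx <- window_indices(seq_codes(s), k)
      m <- m + tabulate(idx, nbins = 4L^k) / (n - k + 1L)
    }
    m <- m / length(seqs)
    if (pseudocount > 0) {
      m <- m + pseudocount
      m <- m / sum(m)
    }
    stats::setNames(m, all_kmers(k))
  }
  out <- list(
    k_range = as.integer(k_range),
    pseudocount = pseudocount,
    log_base = "natural",
    M_pos = lapply(k_range, function(k) mean_profile(pos$seq, k)),
    M_neg = lapply(k_range, function(k) mean_profile(neg$seq, k)),
    n_pos = nrow(pos),
    n_neg = nrow(neg)
  )
  names(out$M_pos) <- as.character(k_range)
  names(out$M_neg) <- as.character(k_range)
  class(out) <- "class_mean_profile"
  out
}

#' @export
print.class_mean_profile <- function(x, ...) {
  cat(sprintf(
    "<class_mean_profile> k = %s, pseudocount = %g, fitted on %d pos / %d neg\n",
    paste(x$k_range, collapse = ","), x$pseudocount, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' k-mer composition bias score
#'
#' The kmerscore of a sequence is the mean, over its `n - k + 1` overlapping
#' k-mer windows, of the natural log ratio of the negative-class to the
#' positive-class mean frequency of the window's k-mer:
#' \deqn{\mathrm{kmerscore} = \frac{1}{n-k+1}\sum_{i=1}^{n-k+1}
#'   \log\frac{M_{neg}(h_i)}{M_{pos}(h_i)}}
#' Higher values indicate a composition more typical of the negative class.
#'
#' @param x Sequence string or single-record [dataset()].
#' @param profile A [fit_class_means()] profile.
#' @param k Word length, must be in `profile$k_range`.
#' @return A single numeric score.
#' @export
kmerscore <- function(x, profile, k) {
  stopifnot(inherits(profile, "class_mean_profile"))
  kk <- as.character(k)
  if (!kk %in% names(profile$M_pos)) {
    stop("k = ", k, " is not in the profile's k_range", call. = FALSE)
  }
  seq <- as_sequence(x)
  n <- nchar(seq)
  if (n < k) stop("sequence", record_tag(x), " is shorter than k = ", k, call. = FALSE)
  mp <- profile$M_pos[[kk]]
  mn <- profile$M_neg[[kk]]
  idx <- window_indices(seq_codes(seq), k)
  if (any(mp[idx] == 0) || any(mn[idx] == 0)) {
    stop(
      "class-mean profile has zero entries for observed k-mers; ",
      "refit with a positive pseudocount",
      call. = FALSE
    )
  }
  mean(log(mn[idx] / mp[idx]))
}

#' Feature names of the 90-dimensional representation
#'
#' @return Character vector of length 90: `"k1_A"` ... `"k3_TTT"` followed by
#'   `"kmerscore_k1"` ... `"kmerscore_k6"`.
#' @export
feature_names <- function() {
  c(
    paste0("k1_", all_kmers(1)),
    paste0("k2_", all_kmers(2)),
    paste0("k3_", all_kmers(3)),
    paste0("kmerscore_k", 1:6)
  )
}

#' Featurize one sequence
#'
#' Assembles the fixed 90-dimensional feature vector: 84 overlapping k-mer
#' frequencies (k = 1, 2, 3; 4 + 16 + 64 entries, each block in lexicographic
#' order) followed by 6 kmerscores (k = 1..6). Requires the sequence to be at
#' least 6 nt (the largest kmerscore word length); shorter inputs are an
#' error rather than silently meaningless scores.
#'
#' @param x Sequence string or single-record [dataset()].
#' @param profile A [fit_class_means()] profile covering k = 1..6.
#' @return Named numeric vector of length 90 (names from [feature_names()]).
#' @export
featurize <- function(x, profile) {
  seq <- as_sequence(x)
  if (nchar(seq) < 6L) {
    stop(
      "sequence", record_tag(x), " is shorter than 6 nt and cannot be featurized",
      call. = FALSE
    )
  }
  v <- c(
    kmer_frequencies(seq, 1L),
    kmer_frequencies(seq, 2L),
    kmer_frequencies(seq, 3L),
    vapply(1:6, function(k) kmerscore(seq, profile, k), numeric(1))
  )
  stats::setNames(v, feature_names())
}

#' Featurize a whole dataset
#'
#' @param data A [dataset()].
#' @param profile A [fit_class_means()] profile.
#' @return Numeric matrix of shape `nrow(data)` x 90, rows aligned to record
#'   order and named by record id.
#' @export
featurize_dataset <- function(data, profile) {
  if (nrow(data) == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = 90L)
    colnames(m) <- feature_names()
    return(m)
  }
  rows <- lapply(seq_len(nrow(data)), function(i) {
    tryCatch(
      featurize(data$seq[i], profile),
      error = function(e) {
        stop(
          "record '", data$id[i], "': ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
  })
  m <- do.call(rbind, rows)
  rownames(m) <- data$id
  m
}

#' Write a feature matrix as TSV
#'
#' @param features Matrix from [featurize_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(id = rownames(features), features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a class-mean profile
#'
#' Profiles are stored as JSON so that a trained model can be shipped with the
#' exact training-time class means and apply them unchanged to new data.
#'
#' @param profile A `class_mean_profile`.
#' @param path File path.
#' @return `path` (write) or the restored profile (read).
#' @export
write_profile <- function(profile, path) {
  jsonlite::write_json(
    list(
      k_range = profile$k_range,
      pseudocount = profile$pseudocount,
      log_base = profile$log_base,
      M_pos = lapply(profile$M_pos, unname),
      M_neg = lapply(profile$M_neg, unname),
      n_pos = profile$n_pos,
      n_neg = profile$n_neg
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    k_range = as.integer(raw$k_range),
    pseudocount = raw$pseudocount,
    log_base = raw$log_base,
    M_pos = lapply(raw$M_pos, as.numeric),
    M_neg = lapply(raw$M_neg, as.numeric),
    n_pos = raw$n_pos,
    n_neg = raw$n_neg
  )
  for (kk in names(out$M_pos)) {
    k <- as.integer(kk)
    names(out$M_pos[[kk]]) <- all_kmers(k)
    names(out$M_neg[[kk]]) <- all_kmers(k)
  }
  class(out) <- "class_mean_profile"
  out
}
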