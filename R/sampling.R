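#' Randomly down-sample negative records
#'
#' Draws a uniform random sample without replacement, the imbalance-handling
#' step that sizes the negative training data to the (augmented) positive
#' training data.
#'
#' @param neg A [dataset()].
#' @param target_n Number of records to keep; must not exceed `nrow(neg)`.
#' @param seed Integer seed; the same seed always yields the same selection.
#' @return A dataset of `target_n` records (original order preserved).
#' @export
downsample_negatives <- function(neg, target_n, seed) {
  if (target_n > nrow(neg)) {
    stop(
      "cannot down-sample ", nrow(neg), " negatives to ", target_n,
      call. = FALSE
    )
  }
  if (target_n == 0L) {
    return(dataset_subset(neg, integer(0), name = "downsampled"))
  }
  keep <- withr::with_seed(seed, sort(sample.int(nrow(neg), target_n)))
  dataset_subset(neg, keep, name = "downsampled")
}

#' Bagging configuration
#'
#' The weighted bagging strategy triples the positive training data
#' (`multiplier = 3`): two-thirds of the draws are bootstrapped from all
#' positives and one-third exclusively from the minority (`subtype = "weak"`)
#' positives, so the model learns features of all positive data rather than
#' only the majority subtype.
#'
#' @param multiplier Output size as a multiple of the input size (default 3).
#' @param weak_fraction Fraction of draws restricted to the weak subtype
#'   (default 1/3).
#' @param seed Integer seed.
#' @return A `bagging_config` list.
#' @export
bagging_config <- function(multiplier = 3L, weak_fraction = 1 / 3, seed = 1L) {
  stopifnot(multiplier >= 1, weak_fraction >= 0, weak_fraction <= 1)
  structure(
    list(
      multiplier = as.integer(multiplier),
      weak_fraction = weak_fraction,
      seed = as.integer(seed)
    ),
    class = "bagging_config"
  )
}

#' Weighted bagging of positive records
#'
#' Produces `multiplier * nrow(pos)` records drawn with replacement:
#' `round((1 - weak_fraction) * multiplier * n)` from the full positive pool
#' and the remainder from the `subtype = "weak"` records only. Drawn records
#' keep their original id with a replicate suffix (`_bag<i>`) so ids stay
#' unique; the column `bag_pool` records which pool each draw came from.
#'
#' @param pos Non-empty positive [dataset()].
#' @param cfg A [bagging_config()].
#' @return A dataset of bagged records with columns `source_id` and
#'   `bag_pool` (`"all"` or `"weak"`) appended.
#' @export
weighted_bagging <- function(pos, cfg = bagging_config()) {
  stopifnot(inherits(cfg, "bagging_config"))
  n <- nrow(pos)
  if (n == 0L) stop("positive dataset is empty", call. = FALSE)
  n_total <- cfg$multiplier * n
  n_all <- as.integer(round((1 - cfg$weak_fraction) * n_total))
  n_weak <- n_total - n_all
  weak_idx <- which(!is.na(pos$subtype) & pos$subtype == "weak")
  if (n_weak > 0L && length(weak_idx) == 0L) {
    stop(
      "weak_fraction > 0 but no record has subtype = 'weak'",
      call. = FALSE
    )
  }
  draws <- withr::with_seed(cfg$seed, {
    c(
      sample.int(n, n_all, replace = TRUE),
      if (n_weak > 0L) weak_idx[sample.int(length(weak_idx), n_weak, replace = TRUE)]
    )
  })
  out <- as.data.frame(pos)[draws, , drop = FALSE]
  out$source_id <- out$id
  out$id <- paste0(out$id, "_bag", seq_len(n_total))
  out$bag_pool <- rep(c("all", "weak"), c(n_all, n_weak))
  rownames(out) <- NULL
  attr(out, "name") <- "bagged"
  class(out) <- c("triplex_dataset", "data.frame")
  out
}

#' Stratified k-fold split plan
#'
#' Assigns every labeled record to one of `n_folds` folds by per-class
#' round-robin after a seeded shuffle, so per-class fold sizes differ by at
#' most one. Records are put in a stable id order before shuffling, making the
#' plan independent of input row order.
#'
#' @param data Labeled [dataset()]; each class must have at least `n_folds`
#'   members.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `split_plan`: list with `n_folds`, `fold` (named integer vector,
#'   record id -> fold), `seed`.
#' @export
stratified_kfold <- function(data, n_folds = 5L, seed = 1L) {
  if (anyNA(data$label)) stop("all records must be labeled", call. = FALSE)
  fold <- integer(nrow(data))
  names(fold) <- data$id
  for (cls in unique(data$label)) {
    ids <- sort(data$id[data$label == cls])
    if (length(ids) < n_folds) {
      stop(
        "class '", cls, "' has ", length(ids), " record(s), fewer than ",
        n_folds, " folds",
        call. = FALSE
      )
    }
    ids <- withr::with_seed(seed, sample(ids))
    fold[ids] <- rep_len(seq_len(n_folds), length(ids))
  }
  structure(
    list(n_folds = as.integer(n_folds), fold = fold, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' Write a split plan as TSV
#'
#' @param plan A [stratified_kfold()] plan.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  utils::write.table(
    data.frame(id = names(plan$fold), fold = unname(plan$fold)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Leave-gene-out split
#'
#' Holds out every transcript variant of one gene as the test set, keeping all
#' remaining records for training. This controls for within-gene sequence
#' redundancy that inflates plain cross-validation performance.
#'
#' @param pos [dataset()] with `gene` labels.
#' @param gene Gene id to hold out.
#' @return List with elements `train` and `test` (disjoint, exhaustive).
#' @export
leave_gene_out_split <- function(pos, gene) {
  genes <- unique(pos$gene[!is.na(pos$gene)])
  if (!gene %in% genes) {
    stop(
      "unknown gene '", gene, "'; available: ",
      paste(utils::head(sort(genes), 10), collapse = ", "),
      call. = FALSE
    )
  }
  test_idx <- which(!is.na(pos$gene) & pos$gene == gene)
  list(
    train = dataset_subset(pos, setdiff(seq_len(nrow(pos)), test_idx), name = "train"),
    test = dataset_subset(pos, test_idx, name = paste0("test_", gene))
  )
}

#' Approximate greedy redundancy filter
#'
#' A deterministic, approximate analogue of identity-threshold redundancy
#' removal (CD-HIT style): records are sorted by decreasing length (ties by
#' id), then processed greedily — a record joins an existing cluster when the
#' cosine similarity between its `word_k`-mer count vector and the cluster
#' representative's is at least `threshold`, otherwise it founds a new
#' cluster. Only representatives are returned. The algorithm differs from
#' CD-HIT and is not bit-compatible with it; the threshold is mapped directly
#' onto the cosine cutoff.
#'
#' @param data Non-empty [dataset()].
#' @param threshold Similarity cutoff in (0, 1], e.g. 0.9 or 0.8.
#' @param word_k Word length for the similarity k-mer vectors (default 5).
#' @return Dataset of cluster representatives (input-order independent).
#' @export
greedy_redundancy_filter <- function(data, threshold = 0.9, word_k = 5L) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(data) == 0L) stop("dataset is empty", call. = FALSE)
  ord <- order(-nchar(data$seq), data$id)
  nb <- 4L^word_k
  vecs <- vapply(data$seq[ord], function(s) {
    if (nchar(s) < word_k) {
      return(rep(0, nb))
    }
    v <- tabulate(window_indices(seq_codes(s), word_k), nbins = nb)
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }, numeric(nb), USE.NAMES = FALSE)
  # vecs: nb x n, unit columns
  reps <- integer(0)
  for (i in seq_along(ord)) {
    if (length(reps) == 0L) {
      reps <- i
      next
    }
    sims <- crossprod(vecs[, reps, drop = FALSE], vecs[, i])
    if (max(sims) < threshold) reps <- c(reps, i)
  }
  keep <- sort(ord[reps])
  dataset_subset(data, keep, name = "nonredundant")
}
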