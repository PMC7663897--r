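#' Base-composition specification
#'
#' Describes one synthetic sequence population by its per-base emission
#' probabilities, a length range, and an optional planted motif.
#'
#' @param name Population name.
#' @param base_probs Probabilities for (A, C, G, T); must sum to 1.
#' @param length_range Integer `c(min, max)` sequence lengths (uniform draw).
#' @param motif Optional motif string over `{A,C,G,T}` planted at a uniform
#'   random position in a fraction `motif_rate` of sequences.
#' @param motif_rate Fraction of sequences receiving the motif.
#' @return A `composition_spec`.
#' @export
composition_spec <- function(name, base_probs, length_range,
                             motif = NULL, motif_rate = 0) {
  stopifnot(length(base_probs) == 4L, length(length_range) == 2L)
  if (abs(sum(base_probs) - 1) > 1e-12) {
    stop("base_probs must sum to 1", call. = FALSE)
  }
  if (any(base_probs < 0)) stop("base_probs must be non-negative", call. = FALSE)
  if (length_range[1] > length_range[2] || length_range[1] < 6L) {
    stop("length_range must satisfy 6 <= min <= max", call. = FALSE)
  }
  if (!is.null(motif)) {
    if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}", call. = FALSE)
    present <- unique(strsplit(motif, "")[[1L]])
    zero <- BASES[base_probs == 0]
    if (any(present %in% zero)) {
      stop("motif contains base(s) with zero emission probability", call. = FALSE)
    }
  }
  structure(
    list(
      name = name, base_probs = stats::setNames(base_probs, BASES),
      length_range = as.integer(length_range), motif = motif,
      motif_rate = motif_rate
    ),
    class = "composition_spec"
  )
}

#' Synthetic study design
#'
#' Defines the compositional structure the classifier exploits: positives
#' drawn from two subtypes — a CG-rich `strong` majority and an AT-rich `weak`
#' minority in roughly 2.5:1 ratio — against an AT-rich negative background,
#' at a configurable class imbalance (about 1:68 for the lncRNA setting,
#' 1:5 for the DNA-site setting). The weak positives differ from the
#' negatives only by a composition offset `delta` (probability mass moved
#' from A/T to C/G); `delta = 0` makes them indistinguishable.
#'
#' Positive records are organized into genes: each gene has an archetype
#' sequence and 1..`max_variants_per_gene` variants generated as point-mutated
#' copies (per-base substitution rate `mutation_rate`), giving leave-gene-out
#' and redundancy filtering realistic within-gene structure.
#'
#' @param mode `"lncrna"` (lengths 200-2000 nt, imbalance 1:68) or
#'   `"dna_site"` (lengths 60-400 nt, imbalance 1:5, no weak subtype).
#' @param n_pos Total positive count; defaults to 70 (lncrna) / 100
#'   (dna_site).
#' @param n_neg Negative count; defaults to `imbalance * n_pos`.
#' @param imbalance Negatives per positive; defaults by mode (68 or 5).
#' @param subtype_ratio Strong:weak ratio among positives (default 2.5; only
#'   for `"lncrna"`).
#' @param delta Composition offset of weak positives from negatives, in
#'   `[0, 0.1]` of probability per base (default 0.05).
#' @param strong_probs,neg_probs Base probabilities of the strong-positive and
#'   negative populations.
#' @param length_range Overrides the mode's default length range.
#' @param max_variants_per_gene Upper bound of variants per gene (default 5).
#' @param mutation_rate Per-base substitution rate between a gene's archetype
#'   and its variants (default 0.02).
#' @param seed Integer seed.
#' @return A `synthetic_design`.
#' @export
synthetic_design <- function(mode = c("lncrna", "dna_site"),
                             n_pos = NULL, n_neg = NULL, imbalance = NULL,
                             subtype_ratio = 2.5, delta = 0.05,
                             strong_probs = c(0.1, 0.4, 0.4, 0.1),
                             neg_probs = c(0.4, 0.1, 0.1, 0.4),
                             length_range = NULL,
                             max_variants_per_gene = 5L,
                             mutation_rate = 0.02,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(imbalance)) imbalance <- if (mode == "lncrna") 68 else 5
  if (is.null(n_pos)) n_pos <- if (mode == "lncrna") 70L else 100L
  if (is.null(n_neg)) n_neg <- as.integer(round(imbalance * n_pos))
  if (is.null(length_range)) {
    length_range <- if (mode == "lncrna") c(200L, 2000L) else c(60L, 400L)
  }
  stopifnot(delta >= 0, delta <= 0.1, mutation_rate >= 0, mutation_rate < 1)
  if (mode == "lncrna") {
    n_pos_weak <- as.integer(round(n_pos / (subtype_ratio + 1)))
    n_pos_strong <- n_pos - n_pos_weak
  } else {
    n_pos_strong <- n_pos
    n_pos_weak <- 0L
  }
  weak_probs <- neg_probs + delta * c(-1, 1, 1, -1)
  if (any(weak_probs < 0)) stop("delta too large for neg_probs", call. = FALSE)
  structure(
    list(
      mode = mode,
      pos_strong = composition_spec("pos_strong", strong_probs, length_range),
      pos_weak = composition_spec("pos_weak", weak_probs, length_range),
      neg = composition_spec("neg", neg_probs, length_range),
      n_pos_strong = n_pos_strong,
      n_pos_weak = n_pos_weak,
      n_neg = as.integer(n_neg),
      max_variants_per_gene = as.integer(max_variants_per_gene),
      mutation_rate = mutation_rate,
      delta = delta,
      seed = as.integer(seed)
    ),
    class = "synthetic_design"
  )
}

random_seq <- function(len, probs) {
  paste(sample(BASES, len, replace = TRUE, prob = probs), collapse = "")
}

mutate_seq <- function(seq, rate, probs) {
  if (rate <= 0) {
    return(seq)
  }
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    chars[hit] <- vapply(chars[hit], function(b) {
      alt <- setdiff(BASES, b)
      p <- probs[alt]
      if (sum(p) == 0) p <- rep(1, 3)
      sample(alt, 1L, prob = p)
    }, character(1))
  }
  paste(chars, collapse = "")
}

# Generate n records from one composition spec, grouped into genes.
generate_population <- function(spec, n, prefix, subtype, label,
                                max_variants, mutation_rate) {
  ids <- character(n)
  seqs <- character(n)
  genes <- character(n)
  i <- 0L
  g <- 0L
  while (i < n) {
    g <- g + 1L
    n_var <- min(sample.int(max_variants, 1L), n - i)
    len <- spec$length_range[1] +
      sample.int(spec$length_range[2] - spec$length_range[1] + 1L, 1L) - 1L
    arch <- random_seq(len, spec$base_probs)
    if (!is.null(spec$motif) && spec$motif_rate > 0) {
      if (stats::runif(1) < spec$motif_rate && nchar(arch) > nchar(spec$motif)) {
        at <- sample.int(nchar(arch) - nchar(spec$motif) + 1L, 1L)
        substr(arch, at, at + nchar(spec$motif) - 1L) <- spec$motif
      }
    }
    gene_id <- sprintf("%s_G%04d", prefix, g)
    for (v in seq_len(n_var)) {
      i <- i + 1L
      ids[i] <- sprintf("%s_%05d", prefix, i)
      seqs[i] <- if (v == 1L) {
        arch
      } else {
        mutate_seq(arch, mutation_rate, spec$base_probs)
      }
      genes[i] <- gene_id
    }
  }
  dataset(ids, seqs,
    label = label, subtype = subtype, gene = genes,
    name = spec$name
  )
}

#' Generate a labeled synthetic dataset pair
#'
#' Draws i.i.d. sequences per the design's composition specs (deterministic
#' given the design seed) and returns positives (with subtype and gene labels)
#' and negatives.
#'
#' @param design A [synthetic_design()].
#' @return List with elements `pos` and `neg` ([dataset()]s).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  withr::with_seed(design$seed, {
    parts <- list()
    if (design$n_pos_strong > 0L) {
      parts$strong <- generate_population(
        design$pos_strong, design$n_pos_strong, "POSS", "strong", "positive",
        design$max_variants_per_gene, design$mutation_rate
      )
    }
    if (design$n_pos_weak > 0L) {
      parts$weak <- generate_population(
        design$pos_weak, design$n_pos_weak, "POSW", "weak", "positive",
        design$max_variants_per_gene, design$mutation_rate
      )
    }
    pos <- if (length(parts) == 2L) {
      dataset_bind(parts$strong, parts$weak, name = "synthetic_pos")
    } else {
      parts[[1L]]
    }
    neg <- generate_population(
      design$neg, design$n_neg, "NEG", NA_character_, "negative",
      design$max_variants_per_gene, design$mutation_rate
    )
    list(pos = pos, neg = neg)
  })
}

#' Per-class base-composition report
#'
#' Mean mononucleotide frequencies per label/subtype group, the sanity check
#' that generated (or real) classes have the expected composition bias.
#'
#' @param data A [dataset()] or a list of datasets (e.g. the output of
#'   [generate_dataset()]).
#' @param path Optional TSV output path.
#' @return Data frame with columns `group`, `n`, `A`, `C`, `G`, `T`.
#' @export
composition_report <- function(data, path = NULL) {
  if (!inherits(data, "triplex_dataset") && is.list(data)) {
    data <- do.call(dataset_bind, c(unname(data), list(name = "combined")))
  }
  if (nrow(data) == 0L) stop("dataset is empty", call. = FALSE)
  grp <- ifelse(is.na(data$subtype),
    as.character(data$label),
    paste(data$label, data$subtype, sep = "_")
  )
  grp[is.na(grp)] <- "unlabeled"
  groups <- sort(unique(grp))
  rows <- lapply(groups, function(g) {
    seqs <- data$seq[grp == g]
    counts <- rep(0, 4)
    total <- 0
    for (s in seqs) {
      counts <- counts + tabulate(seq_codes(s) + 1L, nbins = 4L)
      total <- total + nchar(s)
    }
    fr <- counts / total
    data.frame(
      group = g, n = length(seqs),
      A = fr[1], C = fr[2], G = fr[3], T = fr[4]
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
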