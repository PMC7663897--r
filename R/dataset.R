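#' Construct a sequence dataset
#'
#' A dataset is the package's basic container: a data frame with one row per
#' validated nucleotide sequence. Sequences must already be normalized to the
#' DNA alphabet `A/C/G/T` (see [read_fasta()] for normalization of raw FASTA,
#' including `U -> T` mapping).
#'
#' @param id Character vector of record identifiers, unique within the dataset.
#' @param seq Character vector of sequences over `{A,C,G,T}`, same length as
#'   `id`.
#' @param label Optional class labels, `"positive"` or `"negative"` (`NA`
#'   allowed for unlabeled records).
#' @param subtype Optional positive-subtype tags, `"strong"` or `"weak"`.
#'   The weak subtype is the minority positive class that receives extra
#'   weight during bagging (see [weighted_bagging()]).
#' @param gene Optional gene identifiers used as grouping keys for
#'   leave-gene-out splits.
#' @param name Dataset name, kept as an attribute for logging.
#'
#' @return A `triplex_dataset`: a data frame with columns `id`, `seq`,
#'   `label`, `subtype`, `gene`.
#' @export
dataset <- function(id, seq, label = NA_character_, subtype = NA_character_,
                    gene = NA_character_, name = "dataset") {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length", call. = FALSE)
  }
  d <- data.frame(
    id = id,
    seq = seq,
    label = rep_len(as.character(label), length(id)),
    subtype = rep_len(as.character(subtype), length(id)),
    gene = rep_len(as.character(gene), length(id)),
    stringsAsFactors = FALSE
  )
  attr(d, "name") <- name
  class(d) <- c("triplex_dataset", "data.frame")
  validate_dataset(d)
  d
}

validate_dataset <- function(d) {
  if (nrow(d) == 0L) {
    return(invisible(d))
  }
  if (anyDuplicated(d$id)) {
    dup <- unique(d$id[duplicated(d$id)])
    stop("duplicate record id(s): ", paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!nzchar(d$seq))) {
    stop("empty sequence(s) for record(s): ",
      paste(utils::head(d$id[!nzchar(d$seq)], 5), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- grepl("[^ACGT]", d$seq)
  if (any(bad)) {
    stop(
      "sequence(s) contain characters outside {A,C,G,T}: ",
      paste(utils::head(d$id[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  ok <- is.na(d$label) | d$label %in% c("positive", "negative")
  if (!all(ok)) stop("labels must be 'positive', 'negative' or NA", call. = FALSE)
  ok <- is.na(d$subtype) | d$subtype %in% c("strong", "weak")
  if (!all(ok)) stop("subtypes must be 'strong', 'weak' or NA", call. = FALSE)
  invisible(d)
}

#' @export
print.triplex_dataset <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf(
    "<triplex_dataset '%s'> %d record(s)\n", if (is.null(nm)) "" else nm, nrow(x)
  ))
  if (nrow(x) > 0L) {
    tab <- table(factor(x$label, levels = c("positive", "negative")), useNA = "ifany")
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    cat(
      "  length range:", min(nchar(x$seq)), "-", max(nchar(x$seq)), "nt\n"
    )
  }
  invisible(x)
}

# Row subset preserving class and name attribute.
dataset_subset <- function(d, idx, name = attr(d, "name")) {
  out <- d[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "name") <- name
  class(out) <- c("triplex_dataset", "data.frame")
  out
}

# rbind two datasets (ids must stay unique).
dataset_bind <- function(a, b, name = "bound") {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  dataset(out$id, out$seq, out$label, out$subtype, out$gene, name = name)
}

#' Write a dataset manifest
#'
#' Writes the record table (id, label, subtype, gene) as TSV, the plain-text
#' companion of the FASTA output.
#'
#' @param data A `triplex_dataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(data, path) {
  utils::write.table(
    as.data.frame(data)[, c("id", "label", "subtype", "gene")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
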