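#' Read and normalize a FASTA file
#'
#' Reads nucleotide sequences (lncRNA transcripts or DNA regions) from FASTA,
#' uppercases them, maps `U` to `T` so RNA and DNA inputs are treated
#' uniformly, and validates the result against the `{A,C,G,T}` alphabet.
#' Records containing `N` are either dropped (and logged) or rejected,
#' matching the dataset-cleaning rule of removing N-containing samples;
#' any other IUPAC ambiguity code is always an error, to surface dirty input
#' rather than silently discard it.
#'
#' @param path Path to a FASTA file. Line wrapping, mixed case and CRLF line
#'   endings are tolerated.
#' @param label Optional class label (`"positive"` or `"negative"`) applied to
#'   every record.
#' @param drop_n If `TRUE`, records containing `N` are excluded; their ids are
#'   recorded in the `dropped` attribute of the result (and in `log_path` if
#'   given). If `FALSE` (default), an `N` anywhere is an error.
#' @param log_path Optional path; dropped record ids are written there, one
#'   per line.
#' @param name Dataset name.
#'
#' @return A [dataset()] preserving file order, with attribute `dropped`
#'   (character vector of excluded ids).
#' @export
read_fasta <- function(path, label = NULL, drop_n = FALSE, log_path = NULL,
                       name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s) in '", path, "': ",
      paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)

  other <- grepl("[^ACGTN]", seqs)
  if (any(other)) {
    stop(
      "record(s) with ambiguity codes other than N: ",
      paste(utils::head(ids[other], 5), collapse = ", "),
      call. = FALSE
    )
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  dropped <- character(0)
  if (any(has_n)) {
    if (!drop_n) {
      stop(
        "record(s) contain N (set drop_n = TRUE to exclude them): ",
        paste(utils::head(ids[has_n], 5), collapse = ", "),
        call. = FALSE
      )
    }
    dropped <- ids[has_n]
    ids <- ids[!has_n]
    seqs <- seqs[!has_n]
  }
  if (!is.null(log_path)) writeLines(dropped, log_path)
  if (length(ids) == 0L) {
    stop("all records in '", path, "' were dropped (contained N)", call. = FALSE)
  }
  d <- dataset(ids, seqs,
    label = if (is.null(label)) NA_character_ else label, name = name
  )
  attr(d, "dropped") <- dropped
  d
}

#' Write a dataset to FASTA
#'
#' @param data A [dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  set <- Biostrings::DNAStringSet(data$seq)
  names(set) <- data$id
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read a transcript-to-gene mapping table
#'
#' Reads a two-column TSV (transcript id, gene id; header optional) used to
#' group transcript variants by gene for leave-gene-out validation.
#'
#' @param path Path to the TSV.
#' @return Named character vector: `names` are transcript ids, values gene ids.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("gene map '", path, "' is empty", call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  tab <- utils::read.table(
    text = lines, sep = "\t", header = FALSE,
    colClasses = "character", quote = "", comment.char = ""
  )
  if (ncol(tab) < 2L) stop("gene map must have two tab-separated columns", call. = FALSE)
  # header row is optional: detect common column-name spellings
  first <- tolower(trimws(tab[1L, 1:2]))
  if (any(first %in% c("id", "transcript", "transcript_id", "tx", "tx_id")) ||
    any(first %in% c("gene", "gene_id", "gene_name"))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (nrow(tab) == 0L) {
    warning("gene map '", path, "' has a header but no rows", call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  tx <- trimws(tab[[1L]])
  gene <- trimws(tab[[2L]])
  by_tx <- split(gene, tx)
  multi <- vapply(by_tx, function(g) length(unique(g)) > 1L, logical(1))
  if (any(multi)) {
    stop(
      "transcript(s) mapped to more than one gene: ",
      paste(utils::head(names(by_tx)[multi], 5), collapse = ", "),
      call. = FALSE
    )
  }
  keep <- !duplicated(tx)
  stats::setNames(gene[keep], tx[keep])
}

#' Attach gene labels to a dataset
#'
#' Joins a gene map (from [read_gene_map()]) onto a dataset. Records whose id
#' is missing from the map keep `gene = NA` with a warning.
#'
#' @param data A [dataset()].
#' @param gene_map Named character vector from [read_gene_map()].
#' @return The dataset with its `gene` column filled in.
#' @export
add_gene_labels <- function(data, gene_map) {
  hit <- match(data$id, names(gene_map))
  if (anyNA(hit)) {
    warning(
      sum(is.na(hit)), " record(s) absent from the gene map; gene left NA",
      call. = FALSE
    )
  }
  data$gene <- ifelse(is.na(hit), NA_character_, unname(gene_map[hit]))
  data
}
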