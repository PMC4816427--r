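# Library construction: FASTA ingest, normalization, deduplication and
# length statistics for mature miRNA sequence sets.

#' Construct a miRNA library
#'
#' A `mirna_library` holds identified RNA sequences over \{A,C,G,U\} — the
#' unit of every downstream analysis. Sequences are normalized (T mapped to
#' U, uppercased) and validated; a record with any other character aborts
#' construction with an error naming the offending id.
#'
#' @param ids Character vector of record ids (first header token in FASTA).
#' @param sequences Character vector of sequences, same length as `ids`.
#' @param descriptions Optional character vector of header remainders.
#' @param source Provenance string (file path or `"synthetic"`).
#' @param normalize Apply T->U / uppercase normalization (default `TRUE`).
#' @return An object of class `mirna_library`: a list with `records` (a
#'   data.frame with columns `id`, `description`, `sequence`, `length`),
#'   `alias_map` (`NULL` until [deduplicate()] is applied) and `source`.
#' @export
#' @examples
#' lib <- mirna_library("x", "acgt")
#' lib$records$sequence  # "ACGU"
mirna_library <- function(ids, sequences, descriptions = NULL,
                          source = "in-memory", normalize = TRUE) {
  ids <- as.character(ids)
  sequences <- as.character(sequences)
  if (length(ids) != length(sequences)) {
    stop("ids and sequences must have the same length", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- character(length(ids))
  if (normalize) sequences <- normalize_sequence(sequences)
  if (length(sequences)) validate_sequences(sequences, ids)
  records <- data.frame(
    id = ids,
    description = as.character(descriptions),
    sequence = sequences,
    length = nchar(sequences),
    stringsAsFactors = FALSE
  )
  structure(
    list(records = records, alias_map = NULL, source = source),
    class = "mirna_library"
  )
}

#' @export
print.mirna_library <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("mirna_library: %d record%s (source: %s)\n",
              n, if (n == 1) "" else "s", x$source))
  if (n > 0) {
    cat(sprintf("  lengths: %d-%d nt\n",
                min(x$records$length), max(x$records$length)))
  }
  if (!is.null(x$alias_map)) {
    cat(sprintf("  deduplicated: %d unique sequence%s\n",
                n, if (n == 1) "" else "s"))
  }
  invisible(x)
}

#' @export
summary.mirna_library <- function(object, ...) {
  n <- nrow(object$records)
  out <- list(
    n_records = n,
    n_unique = length(unique(object$records$sequence)),
    deduplicated = !is.null(object$alias_map),
    source = object$source,
    length_range = if (n) range(object$records$length) else c(NA, NA)
  )
  class(out) <- "summary.mirna_library"
  out
}

#' @export
print.summary.mirna_library <- function(x, ...) {
  cat(sprintf("miRNA library (%s)\n", x$source))
  cat(sprintf("  records:        %d\n", x$n_records))
  cat(sprintf("  unique seqs:    %d\n", x$n_unique))
  cat(sprintf("  deduplicated:   %s\n", x$deduplicated))
  if (!is.na(x$length_range[1])) {
    cat(sprintf("  length range:   %d-%d nt\n",
                x$length_range[1], x$length_range[2]))
  }
  invisible(x)
}

#' Read a mature-miRNA FASTA file
#'
#' Parses a FASTA file in the miRBase `mature.fa` header dialect
#' (`>id accession species ...`), normalizes sequences (T->U, uppercase) and
#' optionally filters records by an id prefix such as `"hsa-"` for the human
#' subset. Gzip-compressed input is accepted.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @param species_prefix Optional id prefix filter applied to the first
#'   whitespace-delimited header token.
#' @return A [mirna_library()], records in file order.
#' @export
read_mirna_fasta <- function(path, species_prefix = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  if (is.null(headers)) headers <- character(0)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  sequences <- as.character(set)
  if (!is.null(species_prefix)) {
    keep <- startsWith(ids, species_prefix)
    ids <- ids[keep]
    descriptions <- descriptions[keep]
    sequences <- sequences[keep]
  }
  mirna_library(ids, sequences, descriptions, source = path)
}

#' Write a miRNA library as FASTA
#'
#' @param library A [mirna_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(library, path) {
  stopifnot(inherits(library, "mirna_library"))
  r <- library$records
  headers <- ifelse(nzchar(r$description),
                    paste(r$id, r$description), r$id)
  set <- Biostrings::BStringSet(stats::setNames(r$sequence, headers))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Deduplicate identical sequences annotated under different names
#'
#' Mature miRNA databases list the same sequence under several names;
#' retaining duplicates would inflate every census. Exactly one record per
#' distinct sequence is kept (the first seen, so the result is deterministic
#' given file order), and `alias_map` records all ids that carried each
#' retained sequence. The operation is idempotent.
#'
#' @param library A [mirna_library()].
#' @return A deduplicated [mirna_library()] with `alias_map` populated
#'   (a list keyed by sequence, each element the character vector of ids).
#' @export
deduplicate <- function(library) {
  stopifnot(inherits(library, "mirna_library"))
  r <- library$records
  if (nrow(r) == 0) {
    library$alias_map <- stats::setNames(list(), character(0))
    return(library)
  }
  prior <- library$alias_map  # merge aliases if already deduplicated
  keep <- !duplicated(r$sequence)
  ids_by_seq <- split(r$id, factor(r$sequence, levels = r$sequence[keep]))
  if (!is.null(prior)) {
    ids_by_seq <- lapply(stats::setNames(names(ids_by_seq), names(ids_by_seq)),
                         function(s) {
      unique(c(prior[[s]], ids_by_seq[[s]]))
    })
  }
  library$records <- r[keep, , drop = FALSE]
  rownames(library$records) <- NULL
  library$alias_map <- ids_by_seq
  library
}

#' Length distribution of a library
#'
#' @param library A non-empty [mirna_library()].
#' @return An object of class `length_distribution`: list with `counts`
#'   (named integer vector, names = lengths), `percentages` (unrounded,
#'   `100 * count / n_total`), `percentages_rounded` (half-away-from-zero to
#'   integers, the convention used for printed figures) and `n_total`.
#' @export
length_distribution <- function(library) {
  stopifnot(inherits(library, "mirna_library"))
  n <- nrow(library$records)
  if (n == 0) stop("length distribution is undefined for an empty library",
                   call. = FALSE)
  tab <- table(library$records$length)
  counts <- stats::setNames(as.integer(tab), names(tab))
  pct <- 100 * counts / n
  structure(
    list(counts = counts,
         percentages = pct,
         percentages_rounded = round_half_up(pct),
         n_total = n),
    class = "length_distribution"
  )
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("Length distribution over %d sequences\n", x$n_total))
  df <- data.frame(length = as.integer(names(x$counts)),
                   count = x$counts,
                   percent = x$percentages_rounded,
                   row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabular and JSON library summaries
#'
#' `write_library_tsv()` writes one row per record (`id`, `sequence`,
#' `length`); `library_summary_json()` returns the JSON summary string
#' (record count, unique-sequence count, length histogram).
#'
#' @param library A [mirna_library()].
#' @param path Output path for the TSV.
#' @return `write_library_tsv()`: `path`, invisibly.
#'   `library_summary_json()`: a JSON string.
#' @export
write_library_tsv <- function(library, path) {
  stopifnot(inherits(library, "mirna_library"))
  utils::write.table(
    library$records[, c("id", "sequence", "length")],
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
library_summary_json <- function(library) {
  stopifnot(inherits(library, "mirna_library"))
  hist <- if (nrow(library$records)) {
    tab <- table(library$records$length)
    as.list(stats::setNames(as.integer(tab), names(tab)))
  } else {
    stats::setNames(list(), character(0))
  }
  jsonlite::toJSON(
    list(n_records = nrow(library$records),
         n_unique = length(unique(library$records$sequence)),
         length_histogram = hist),
    auto_unbox = TRUE, pretty = TRUE
  )
}
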