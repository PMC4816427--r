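# Nucleotide composition: pooled base content, positional occupancy
# matrices anchored at either end, terminal-base summaries, and
# purine/pyrimidine-richness classification.

#' Pooled nucleotide content of a library
#'
#' Counts every nucleotide of every sequence and reports fractions of the
#' pooled total (e.g. the human mature set shows a prevalence of G and U
#' over A and C).
#'
#' @param library A non-empty [mirna_library()].
#' @return An object of class `composition_profile`: list with `counts`
#'   (named integer, A/C/G/U), `fractions` (sum to 1), `n_nucleotides`.
#' @export
base_content <- function(library) {
  stopifnot(inherits(library, "mirna_library"))
  if (nrow(library$records) == 0) {
    stop("base content is undefined for an empty library", call. = FALSE)
  }
  chars <- unlist(seq_chars(library$records$sequence), use.names = FALSE)
  counts <- vapply(RNA_BASES, function(b) sum(chars == b), integer(1))
  structure(
    list(counts = counts,
         fractions = counts / sum(counts),
         n_nucleotides = sum(counts)),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("Nucleotide content over %d nt\n", x$n_nucleotides))
  df <- data.frame(base = names(x$counts), count = x$counts,
                   percent = round_half_up(100 * x$fractions),
                   row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Positional nucleotide frequency matrix
#'
#' Per-position base counts with sequences anchored either at the 5' end
#' (position p = p-th base from the 5' end) or at the 3' end (p-th base from
#' the 3' end). Sequences shorter than p do not contribute at position p, so
#' the per-position coverage `n_covering` is non-increasing. Positions are
#' 1-based, matching the field's "seed = positions 2-8" convention.
#'
#' @param library A non-empty [mirna_library()].
#' @param anchor `"five_prime"` (default) or `"three_prime"`.
#' @return A matrix of class `positional_frequency_matrix` (rows =
#'   positions, columns = A/C/G/U) with attributes `anchor` and
#'   `n_covering` (integer vector of per-position sequence counts).
#' @export
positional_frequency <- function(library,
                                 anchor = c("five_prime", "three_prime")) {
  stopifnot(inherits(library, "mirna_library"))
  anchor <- match.arg(anchor)
  seqs <- library$records$sequence
  if (length(seqs) == 0) {
    stop("positional frequencies are undefined for an empty library",
         call. = FALSE)
  }
  chars <- seq_chars(seqs)
  if (anchor == "three_prime") chars <- lapply(chars, rev)
  maxlen <- max(lengths(chars))
  counts <- matrix(0L, nrow = maxlen, ncol = 4,
                   dimnames = list(seq_len(maxlen), RNA_BASES))
  for (cc in chars) {
    idx <- cbind(seq_along(cc), match(cc, RNA_BASES))
    counts[idx] <- counts[idx] + 1L
  }
  structure(counts,
            anchor = anchor,
            n_covering = as.integer(rowSums(counts)),
            class = c("positional_frequency_matrix", "matrix", "array"))
}

#' @export
print.positional_frequency_matrix <- function(x, ...) {
  cat(sprintf("Positional frequency matrix (%s anchor, %d positions)\n",
              attr(x, "anchor"), nrow(x)))
  m <- unclass(x)
  attr(m, "anchor") <- NULL
  attr(m, "n_covering") <- NULL
  print(m)
  invisible(x)
}

#' Terminal-base summary
#'
#' Counts of each base at the first (5') and last (3') position of every
#' sequence, stratified by sequence length (strata are the lengths observed
#' in the library).
#'
#' @param library A non-empty [mirna_library()].
#' @return A data.frame with columns `end` (`"five_prime"`/`"three_prime"`),
#'   `length`, `base`, `count`; rows with zero counts are included so the
#'   table is a complete grid over observed lengths.
#' @export
terminal_bases <- function(library) {
  stopifnot(inherits(library, "mirna_library"))
  r <- library$records
  if (nrow(r) == 0) {
    stop("terminal bases are undefined for an empty library", call. = FALSE)
  }
  first <- substr(r$sequence, 1L, 1L)
  last <- substr(r$sequence, r$length, r$length)
  lens <- sort(unique(r$length))
  grid <- expand.grid(end = c("five_prime", "three_prime"),
                      length = lens, base = RNA_BASES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  count_one <- function(end, len, base) {
    b <- if (end == "five_prime") first else last
    sum(r$length == len & b == base)
  }
  grid$count <- mapply(count_one, grid$end, grid$length, grid$base)
  grid[order(grid$end, grid$length, grid$base), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Purine/pyrimidine-richness classification
#'
#' Classifies each sequence by its purine (A+G) and pyrimidine (C+U)
#' fractions: a sequence is called rich when the relevant fraction strictly
#' exceeds `threshold` (default 0.70, i.e. "over 70%"), and flagged highly
#' rich when it reaches `highly_rich_threshold` (default 0.90). Reported
#' percentages are rounded half away from zero to integers, the convention
#' that reproduces published tables.
#'
#' @param x A [mirna_library()] or a character vector of sequences.
#' @param threshold Richness call threshold on the fraction scale
#'   (strict `>`; default 0.70).
#' @param highly_rich_threshold Highly-rich flag threshold (`>=`; default
#'   0.90).
#' @param ids Optional ids when `x` is a character vector.
#' @return A data.frame with one row per sequence: `id`, `sequence`,
#'   `purine_fraction`, `pyrimidine_fraction`, `purine_pct`,
#'   `pyrimidine_pct` (rounded integers), `call` (`"purine_rich"`,
#'   `"pyrimidine_rich"` or `"neither"`), `richness_pct` (rounded percent of
#'   the dominant class) and `highly_rich`.
#' @export
#' @examples
#' classify_pp(c(a = "GGGAAAAGGAAGGGGGAGGA"))$call  # "purine_rich"
classify_pp <- function(x, threshold = 0.70, highly_rich_threshold = 0.90,
                        ids = NULL) {
  if (inherits(x, "mirna_library")) {
    seqs <- x$records$sequence
    ids <- x$records$id
  } else {
    seqs <- normalize_sequence(as.character(x))
    if (is.null(ids)) {
      ids <- if (!is.null(names(x))) names(x) else
        sprintf("seq%d", seq_along(seqs))
    }
    validate_sequences(seqs, ids)
  }
  chars <- seq_chars(seqs)
  pur <- vapply(chars, function(cc) sum(cc %in% c("A", "G")), numeric(1))
  n <- lengths(chars)
  purine_fraction <- pur / n
  pyrimidine_fraction <- 1 - purine_fraction
  call <- ifelse(purine_fraction > threshold, "purine_rich",
                 ifelse(pyrimidine_fraction > threshold,
                        "pyrimidine_rich", "neither"))
  dominant <- pmax(purine_fraction, pyrimidine_fraction)
  data.frame(
    id = ids,
    sequence = seqs,
    purine_fraction = purine_fraction,
    pyrimidine_fraction = pyrimidine_fraction,
    purine_pct = round_half_up(100 * purine_fraction),
    pyrimidine_pct = round_half_up(100 * pyrimidine_fraction),
    call = call,
    richness_pct = round_half_up(100 * dominant),
    highly_rich = dominant >= highly_rich_threshold,
    stringsAsFactors = FALSE
  )
}
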