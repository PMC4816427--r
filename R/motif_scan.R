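# Fixed-motif scanning (including the 5'-UGUGU-3' interferon-induction
# motif) and alternating-GU tract detection.

#' Scan a sequence for exact occurrences of a motif
#'
#' Finds every occurrence (overlapping mode, the default — occurrences of
#' UGUGU inside GU-repeat regions overlap) or the leftmost-greedy
#' non-overlapping occurrences of an exact \{A,C,G,U\} motif. Coordinates
#' are 1-based and inclusive.
#'
#' @param sequence A single sequence (character scalar) or a
#'   [mirna_library()] record row is not required — pass the sequence string.
#' @param motif Motif string over \{A,C,G,U\} (T is normalized to U).
#' @param overlapping Report overlapping occurrences (default `TRUE`).
#' @param id Optional record id carried into the output.
#' @return A data.frame with columns `id`, `motif`, `start`, `end`,
#'   `overlapping`; zero rows when the motif does not occur.
#' @export
#' @examples
#' scan_motif("UGAGUGUGUGUGUGUGAGUGUGU", "UGUGU")$start  # 5 7 9 11 19
scan_motif <- function(sequence, motif, overlapping = TRUE, id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_sequence(sequence)
  validate_sequences(sequence, id)
  motif <- normalize_sequence(motif)
  validate_motif(motif)
  m <- nchar(motif)
  if (m > nchar(sequence)) {
    starts <- integer(0)
  } else if (overlapping) {
    hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
    starts <- if (hits[1] == -1L) integer(0) else as.integer(hits)
  } else {
    hits <- gregexpr(motif, sequence, fixed = TRUE)[[1]]
    starts <- if (hits[1] == -1L) integer(0) else as.integer(hits)
  }
  data.frame(
    id = rep(id, length(starts)),
    motif = rep(motif, length(starts)),
    start = starts,
    end = starts + m - 1L,
    overlapping = rep(overlapping, length(starts)),
    stringsAsFactors = FALSE
  )
}

#' Census of motif-containing sequences in a library
#'
#' Returns the subset of records containing at least one occurrence of the
#' motif, with per-record hit counts. The default motif is the 5'-UGUGU-3'
#' pentamer associated with innate immune (interferon) stimulation by small
#' RNAs.
#'
#' @param library A [mirna_library()] (deduplicate first for census counts).
#' @param motif Motif string (default `"UGUGU"`).
#' @param overlapping Count overlapping occurrences (default `TRUE`).
#' @return A data.frame with columns `id`, `sequence`, `n_hits` (>= 1),
#'   records without occurrences excluded, in library order.
#' @export
find_iim <- function(library, motif = "UGUGU", overlapping = TRUE) {
  stopifnot(inherits(library, "mirna_library"))
  motif <- normalize_sequence(motif)
  validate_motif(motif)
  r <- library$records
  n_hits <- vapply(seq_len(nrow(r)), function(i) {
    nrow(scan_motif(r$sequence[i], motif, overlapping, id = r$id[i]))
  }, integer(1))
  out <- data.frame(id = r$id, sequence = r$sequence, n_hits = n_hits,
                    stringsAsFactors = FALSE)
  out <- out[out$n_hits >= 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximal alternating-GU tracts
#'
#' Finds every maximal run of strictly alternating G and U (either phase:
#' `GUGU...` or `UGUG...`) of at least `min_length` nucleotides. Maximality
#' means the run cannot be extended in either direction while remaining a
#' strict G/U alternation, so reported tracts never overlap.
#'
#' @param sequence A single sequence string.
#' @param min_length Minimum tract length in nucleotides (default 5, >= 2).
#' @param id Optional record id carried into the output.
#' @return A data.frame with columns `id`, `start`, `end`, `tract`,
#'   `length`, in ascending start order.
#' @export
#' @examples
#' gu_tracts("UGAGUGUGUGUGUGUGAGUGUGU")$tract  # 13-nt and 5-nt tracts
gu_tracts <- function(sequence, min_length = 5L, id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            min_length >= 2L)
  sequence <- normalize_sequence(sequence)
  validate_sequences(sequence, id)
  cc <- seq_chars(sequence)[[1]]
  n <- length(cc)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (cc[i] %in% c("G", "U")) {
      j <- i
      while (j < n && cc[j + 1L] %in% c("G", "U") && cc[j + 1L] != cc[j]) {
        j <- j + 1L
      }
      if (j - i + 1L >= min_length) {
        starts <- c(starts, i)
        ends <- c(ends, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(
    id = rep(id, length(starts)),
    start = starts,
    end = ends,
    tract = if (length(starts)) substring(sequence, starts, ends)
            else character(0),
    length = ends - starts + 1L,
    stringsAsFactors = FALSE
  )
}

#' Is a sequence GU-rich?
#'
#' A sequence is called GU-rich when it carries at least one maximal
#' alternating-G/U tract of `min_length` nucleotides or more. No formal
#' community definition of GU-richness exists for mature miRNAs; this
#' presence rule (default tract >= 5 nt) is the weakest criterion satisfied
#' by published GU-rich lists and is configurable.
#'
#' @inheritParams gu_tracts
#' @return `TRUE` or `FALSE`.
#' @export
is_gu_rich <- function(sequence, min_length = 5L, id = NA_character_) {
  nrow(gu_tracts(sequence, min_length = min_length, id = id)) > 0L
}

#' GU-rich subset of a library
#'
#' @param library A [mirna_library()].
#' @param min_length Minimum alternating-tract length (default 5).
#' @return A data.frame `id`, `sequence`, `n_tracts`, `longest_tract` for the
#'   GU-rich records, in library order.
#' @export
find_gu_rich <- function(library, min_length = 5L) {
  stopifnot(inherits(library, "mirna_library"))
  r <- library$records
  rows <- lapply(seq_len(nrow(r)), function(i) {
    tr <- gu_tracts(r$sequence[i], min_length = min_length, id = r$id[i])
    if (nrow(tr) == 0L) return(NULL)
    data.frame(id = r$id[i], sequence = r$sequence[i],
               n_tracts = nrow(tr), longest_tract = max(tr$length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), sequence = character(0),
                      n_tracts = integer(0), longest_tract = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
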