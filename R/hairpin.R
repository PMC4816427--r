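# Intramolecular stem-loop (hairpin) enumeration within single short RNA
# sequences, tetraloop classification and a simple stability score.
#
# Stems are contiguous nested base pairs grown outward from the closing
# pair (no bulges or internal loops): mature miRNAs are at most ~27 nt, and
# contiguous stems keep the enumerator exactly verifiable against a
# brute-force oracle. This deliberately diverges from thermodynamic folding
# programs; the score below is a pairing-weight surrogate, not a free
# energy in kcal/mol.

pair_ok <- function(a, b, allow_wobble = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  wobble <- (a == "G" & b == "U") | (a == "U" & b == "G")
  wc | (allow_wobble & wobble)
}

new_hairpin <- function(id, pairs, pair_bases, loop_start, loop_end,
                        loop_seq, closing_pair) {
  hp <- structure(
    list(id = id,
         pairs = pairs,                      # outermost first, cols i, j
         pair_bases = pair_bases,            # bases at i and j, same order
         stem_length = nrow(pairs),
         loop_start = loop_start,
         loop_end = loop_end,
         loop_seq = loop_seq,
         closing_pair = closing_pair,        # c(5' base, 3' base), innermost
         score = NA_real_),
    class = "hairpin"
  )
  hp$score <- stability_score(hp)
  hp
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf(
    "hairpin%s: stem %d bp, loop %d-%d \"%s\", closing pair %s-%s, score %.1f\n",
    if (is.na(x$id)) "" else paste0(" [", x$id, "]"),
    x$stem_length, x$loop_start, x$loop_end, x$loop_seq,
    x$closing_pair[1], x$closing_pair[2], x$score))
  invisible(x)
}

#' Enumerate candidate hairpins in a sequence
#'
#' For every loop placement with loop length in `[loop_min, loop_max]`, the
#' stem is grown outward from the closing pair (the pair adjacent to the
#' loop) while bases pair — Watson-Crick (A:U, G:C) or, by default, G:U
#' wobble — with no bulges. Only maximal stems are reported (one candidate
#' per loop placement, grown until pairing fails or a sequence end is
#' reached), and only those with `stem_length >= min_stem`. A hairpin need
#' not span the whole sequence; dangling ends are unconstrained.
#'
#' @param sequence A single sequence string.
#' @param min_stem Minimum stem length in base pairs (default 3).
#' @param loop_min,loop_max Loop length bounds in nucleotides (defaults 3
#'   and 8; `loop_min >= 3`).
#' @param allow_wobble Permit G:U pairs in the stem (default `TRUE`).
#' @param id Optional record id carried into each hairpin.
#' @return A list of `hairpin` objects sorted by (descending stem length,
#'   ascending loop length, ascending loop start); empty list when no
#'   hairpin exists. Each hairpin holds 1-based `pairs` (matrix, outermost
#'   first), `stem_length`, `loop_start`/`loop_end`/`loop_seq`,
#'   `closing_pair` (5' base, 3' base of the innermost pair) and `score`.
#' @export
#' @examples
#' hp <- enumerate_hairpins("GGGAAAACCC")[[1]]
#' hp$loop_seq  # "AAAA"
enumerate_hairpins <- function(sequence, min_stem = 3L, loop_min = 3L,
                               loop_max = 8L, allow_wobble = TRUE,
                               id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            loop_min >= 3L, loop_min <= loop_max, min_stem >= 1L)
  sequence <- normalize_sequence(sequence)
  validate_sequences(sequence, id)
  cc <- seq_chars(sequence)[[1]]
  n <- length(cc)
  out <- list()
  for (loop_len in seq(loop_min, loop_max)) {
    if (loop_len + 2L > n) break
    for (ls in 2L:(n - loop_len)) {
      le <- ls + loop_len - 1L
      i <- ls - 1L
      j <- le + 1L
      s <- 0L
      while (i >= 1L && j <= n && pair_ok(cc[i], cc[j], allow_wobble)) {
        s <- s + 1L
        i <- i - 1L
        j <- j + 1L
      }
      if (s >= min_stem) {
        ii <- (ls - s):(ls - 1L)
        jj <- (le + s):(le + 1L)
        pairs <- cbind(i = ii, j = jj)
        out[[length(out) + 1L]] <- new_hairpin(
          id = id, pairs = pairs,
          pair_bases = cbind(i = cc[ii], j = cc[jj]),
          loop_start = ls, loop_end = le,
          loop_seq = substr(sequence, ls, le),
          closing_pair = c(cc[ls - 1L], cc[le + 1L])
        )
      }
    }
  }
  if (length(out) > 1L) {
    key <- vapply(out, function(h) {
      c(-h$stem_length, h$loop_end - h$loop_start + 1L, h$loop_start)
    }, numeric(3))
    out <- out[order(key[1, ], key[2, ], key[3, ])]
  }
  out
}

#' Best hairpin of a sequence
#'
#' The first element of the sorted [enumerate_hairpins()] output (longest
#' stem, then shortest loop, then leftmost), or `NULL` if the sequence
#' admits no qualifying hairpin.
#'
#' @inheritParams enumerate_hairpins
#' @return A `hairpin` object or `NULL`.
#' @export
best_hairpin <- function(sequence, min_stem = 3L, loop_min = 3L,
                         loop_max = 8L, allow_wobble = TRUE,
                         id = NA_character_) {
  hps <- enumerate_hairpins(sequence, min_stem = min_stem,
                            loop_min = loop_min, loop_max = loop_max,
                            allow_wobble = allow_wobble, id = id)
  if (length(hps)) hps[[1L]] else NULL
}

#' Default tetraloop motif set
#'
#' The stable tetraloop sequences tabulated for mature miRNA hairpins:
#' UUCG, GAAA, GCAA, GAGA, GUGA, GGAA, CUUG, UUUG, plus UUUU (tabulated
#' alongside them in the reference census).
#'
#' @return Character vector of 4-mers.
#' @export
tetraloop_motifs <- function() {
  c("UUCG", "GAAA", "GCAA", "GAGA", "GUGA", "GGAA", "CUUG", "UUUG", "UUUU")
}

#' Classify a hairpin's loop against a tetraloop filter cascade
#'
#' Computes the three cascade flags used for tetraloop censuses: loop is a
#' 4-mer in the motif set; stem has at least 3 base pairs; and the closing
#' pair (the innermost stem pair, adjacent to the loop) is C-G. The closing
#' pair test is on the unordered pair \{C,G\} by default; `"strict"`
#' requires C on the 5' side and G on the 3' side.
#'
#' @param hairpin A `hairpin` object from [enumerate_hairpins()].
#' @param motif_set Character vector of admissible loop 4-mers (default
#'   [tetraloop_motifs()]).
#' @param closing_orientation `"unordered"` (default) or `"strict"`.
#' @return A list of class `tetraloop_record`: `hairpin`,
#'   `loop_in_motif_set`, `stem_ge_3`, `closing_pair_cg`.
#' @export
classify_tetraloop <- function(hairpin, motif_set = tetraloop_motifs(),
                               closing_orientation = c("unordered", "strict")) {
  stopifnot(inherits(hairpin, "hairpin"))
  closing_orientation <- match.arg(closing_orientation)
  loop_len <- hairpin$loop_end - hairpin$loop_start + 1L
  cp <- hairpin$closing_pair
  cg <- if (closing_orientation == "unordered") {
    setequal(cp, c("C", "G"))
  } else {
    cp[1] == "C" && cp[2] == "G"
  }
  structure(
    list(hairpin = hairpin,
         loop_in_motif_set = loop_len == 4L && hairpin$loop_seq %in% motif_set,
         stem_ge_3 = hairpin$stem_length >= 3L,
         closing_pair_cg = cg),
    class = "tetraloop_record"
  )
}

#' Simple hairpin stability score
#'
#' A pairing-weight surrogate for stem stability: the sum over stem pairs
#' of 3 (G:C), 2 (A:U) or 1 (G:U), minus a loop penalty of
#' `0.5 * (loop length - 3)`. Higher is more stable. This is a documented
#' ranking heuristic, not a free energy in kcal/mol.
#'
#' @param hairpin A `hairpin` object.
#' @return The numeric score.
#' @export
stability_score <- function(hairpin) {
  stopifnot(inherits(hairpin, "hairpin"), nrow(hairpin$pairs) >= 1L)
  key <- apply(hairpin$pair_bases, 1L, function(p) {
    paste(sort(p), collapse = "")
  })
  weights <- c(CG = 3, AU = 2, GU = 1)
  unname(sum(weights[key]) -
           0.5 * (hairpin$loop_end - hairpin$loop_start + 1L - 3L))
}

#' Dot-bracket string for a hairpin
#'
#' Encodes the hairpin in standard dot-bracket secondary-structure
#' notation: `(` and `)` at paired positions, `.` elsewhere.
#'
#' @param hairpin A `hairpin` object.
#' @param n Sequence length (the string length to produce).
#' @return A character scalar of length-`n` structure symbols.
#' @export
dot_bracket <- function(hairpin, n) {
  stopifnot(inherits(hairpin, "hairpin"), n >= max(hairpin$pairs))
  sym <- rep(".", n)
  sym[hairpin$pairs[, "i"]] <- "("
  sym[hairpin$pairs[, "j"]] <- ")"
  paste(sym, collapse = "")
}

#' Tetraloop filter cascade over a library
#'
#' Mirrors the three-column census layout: per tetraloop motif, the number
#' of sequences that (1) can form a hairpin with that loop, (2) with a stem
#' of at least 3 base pairs, (3) additionally with a C-G closing pair.
#' Sequences are counted by their best qualifying hairpin by default
#' (`count = "best"`); `count = "all"` credits a sequence at a stage if any
#' of its motif-loop hairpins passes that stage. Stage counts are
#' non-increasing left to right in either mode.
#'
#' @param library A [mirna_library()].
#' @param motif_set Loop 4-mers to tabulate (default [tetraloop_motifs()]).
#' @param allow_wobble Permit G:U stem pairs (default `TRUE`).
#' @param closing_orientation Passed to [classify_tetraloop()].
#' @param count `"best"` (default) or `"all"`.
#' @return A data.frame with columns `motif`, `hairpin_formation`,
#'   `stem_ge_3`, `stem_ge_3_closing_cg`, plus a `"Total"` row.
#' @export
tetraloop_cascade <- function(library, motif_set = tetraloop_motifs(),
                              allow_wobble = TRUE,
                              closing_orientation = c("unordered", "strict"),
                              count = c("best", "all")) {
  stopifnot(inherits(library, "mirna_library"))
  closing_orientation <- match.arg(closing_orientation)
  count <- match.arg(count)
  r <- library$records
  tallies <- matrix(0L, nrow = length(motif_set), ncol = 3,
                    dimnames = list(motif_set, NULL))
  for (idx in seq_len(nrow(r))) {
    hps <- enumerate_hairpins(r$sequence[idx], min_stem = 1L,
                              loop_min = 4L, loop_max = 4L,
                              allow_wobble = allow_wobble, id = r$id[idx])
    if (!length(hps)) next
    loops <- vapply(hps, function(h) h$loop_seq, character(1))
    for (m in motif_set) {
      sub <- hps[loops == m]
      if (!length(sub)) next
      recs <- lapply(sub, classify_tetraloop, motif_set = motif_set,
                     closing_orientation = closing_orientation)
      if (count == "best") recs <- recs[1L]  # sub inherits enumeration order
      stage1 <- TRUE
      stage2 <- any(vapply(recs, function(x) x$stem_ge_3, logical(1)))
      stage3 <- any(vapply(recs, function(x) x$stem_ge_3 && x$closing_pair_cg,
                           logical(1)))
      tallies[m, ] <- tallies[m, ] + c(stage1, stage2, stage3)
    }
  }
  out <- data.frame(
    motif = rownames(tallies),
    hairpin_formation = tallies[, 1],
    stem_ge_3 = tallies[, 2],
    stem_ge_3_closing_cg = tallies[, 3],
    stringsAsFactors = FALSE
  )
  total <- data.frame(motif = "Total",
                      hairpin_formation = sum(tallies[, 1]),
                      stem_ge_3 = sum(tallies[, 2]),
                      stem_ge_3_closing_cg = sum(tallies[, 3]),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}

#' Loop-size census of best hairpins
#'
#' Number of sequences whose best hairpin (default parameters) has each
#' loop length, over the loop range.
#'
#' @param library A [mirna_library()].
#' @param min_stem,loop_min,loop_max,allow_wobble Passed to
#'   [best_hairpin()].
#' @return A data.frame `loop_length`, `n_sequences` covering
#'   `loop_min:loop_max`, plus an `n_foldable` attribute (sequences with
#'   any qualifying hairpin).
#' @export
loop_size_census <- function(library, min_stem = 3L, loop_min = 3L,
                             loop_max = 8L, allow_wobble = TRUE) {
  stopifnot(inherits(library, "mirna_library"))
  r <- library$records
  loops <- vapply(seq_len(nrow(r)), function(i) {
    hp <- best_hairpin(r$sequence[i], min_stem = min_stem,
                       loop_min = loop_min, loop_max = loop_max,
                       allow_wobble = allow_wobble, id = r$id[i])
    if (is.null(hp)) NA_integer_ else hp$loop_end - hp$loop_start + 1L
  }, integer(1))
  sizes <- loop_min:loop_max
  out <- data.frame(
    loop_length = sizes,
    n_sequences = vapply(sizes, function(s) sum(loops == s, na.rm = TRUE),
                         integer(1))
  )
  attr(out, "n_foldable") <- sum(!is.na(loops))
  out
}
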