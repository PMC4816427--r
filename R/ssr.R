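# Simple sequence repeat (SSR / microsatellite) detection for unit sizes
# 1-5 under a minimum-three-complete-repeats rule, with library-level
# totals and relative counts ("repeats per miRNA on average").

# TRUE iff the unit is not itself a repetition of a shorter string
# ("GU" is primitive, "GUGU" is not).
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && unit == strrep(substr(unit, 1L, d), k / d)) {
      return(FALSE)
    }
  }
  TRUE
}

# Canonical class of a repeat unit: dinucleotides are grouped as the
# unordered pair written "XY/YX" (e.g. GU and UG both belong to "GU/UG");
# other unit lengths use the lexicographically smallest rotation.
canonical_ssr_class <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(unit)
  rotations <- vapply(seq_len(k), function(s) {
    paste0(substr(unit, s, k), substr(unit, 1L, s - 1L))
  }, character(1))
  if (k == 2L) {
    return(paste(sort(unique(rotations)), collapse = "/"))
  }
  min(rotations)
}

#' Detect simple sequence repeats in one sequence
#'
#' For each unit length 1..`max_unit` independently, finds maximal tracts of
#' tandemly repeated primitive units with at least `min_repeats` complete
#' repeats. Tracts are counted in complete units only (a trailing partial
#' unit does not extend a tract: `"GUGUGUG"` yields (GU)3, the final G
#' excluded). Within one unit length, scanning is leftmost-greedy and
#' non-overlapping; tracts of different unit lengths may overlap each other
#' (the per-unit-length censuses are independent). Non-primitive units are
#' never reported, so an (AA)3 inside an (A)6 run is excluded.
#'
#' @param sequence A single sequence string.
#' @param min_repeats Minimum complete repeats per tract (default 3, >= 2).
#' @param max_unit Maximum unit length, 1-5 (default 5).
#' @param id Optional record id carried into the output.
#' @return A data.frame with columns `id`, `unit` (as it occurs),
#'   `canonical_class`, `unit_length`, `repeat_count`, `start`, `end`,
#'   `tract_length`, sorted by (`unit_length`, `start`).
#' @export
#' @examples
#' find_ssrs("UGGGCUGGGCUGGGCUGGGC")  # (UGGGC)4
find_ssrs <- function(sequence, min_repeats = 3L, max_unit = 5L,
                      id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            min_repeats >= 2L, max_unit >= 1L, max_unit <= 5L)
  sequence <- normalize_sequence(sequence)
  validate_sequences(sequence, id)
  n <- nchar(sequence)
  rows <- list()
  for (k in seq_len(max_unit)) {
    i <- 1L
    while (i + k * min_repeats - 1L <= n) {
      unit <- substr(sequence, i, i + k - 1L)
      if (is_primitive_unit(unit)) {
        r <- 1L
        while (substr(sequence, i + r * k, i + (r + 1L) * k - 1L) == unit) {
          r <- r + 1L
        }
        left_maximal <- (i - k < 1L) || substr(sequence, i - k, i - 1L) != unit
        if (r >= min_repeats && left_maximal) {
          rows[[length(rows) + 1L]] <- data.frame(
            id = id, unit = unit,
            canonical_class = canonical_ssr_class(unit),
            unit_length = k, repeat_count = r,
            start = i, end = i + r * k - 1L,
            tract_length = r * k,
            stringsAsFactors = FALSE
          )
          i <- i + r * k
          next
        }
      }
      i <- i + 1L
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), unit = character(0),
                      canonical_class = character(0),
                      unit_length = integer(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0),
                      tract_length = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$unit_length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Library-level SSR summary
#'
#' Pools [find_ssrs()] tracts over all records and reports totals per unit
#' length, totals per canonical class, and relative counts (tracts divided
#' by the number of miRNAs — "repeats per miRNA on average"). Relative
#' counts are reported to two decimals (half away from zero) in formatted
#' output; the object keeps them unrounded.
#'
#' @param library A deduplicated, non-empty [mirna_library()].
#' @param min_repeats Minimum complete repeats per tract (default 3).
#' @param max_unit Maximum unit length (default 5).
#' @return An object of class `ssr_summary`: list with `totals` (named by
#'   unit length "1".."5"), `class_totals` (list per unit length of named
#'   class counts), `relative_counts`, `grand_total`, `grand_relative`,
#'   `n_mirnas`, and `tracts` (the pooled per-tract data.frame).
#' @export
ssr_summary <- function(library, min_repeats = 3L, max_unit = 5L) {
  stopifnot(inherits(library, "mirna_library"))
  r <- library$records
  if (nrow(r) == 0L) stop("SSR summary is undefined for an empty library",
                          call. = FALSE)
  tracts <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    find_ssrs(r$sequence[i], min_repeats = min_repeats,
              max_unit = max_unit, id = r$id[i])
  }))
  unit_levels <- as.character(seq_len(max_unit))
  totals <- stats::setNames(integer(max_unit), unit_levels)
  class_totals <- stats::setNames(vector("list", max_unit), unit_levels)
  for (k in unit_levels) class_totals[[k]] <- integer(0)
  if (nrow(tracts)) {
    tab <- table(factor(tracts$unit_length, levels = unit_levels))
    totals <- stats::setNames(as.integer(tab), unit_levels)
    for (k in unit_levels) {
      sub <- tracts[tracts$unit_length == as.integer(k), , drop = FALSE]
      if (nrow(sub)) {
        ctab <- sort(table(sub$canonical_class), decreasing = TRUE)
        class_totals[[k]] <- stats::setNames(as.integer(ctab), names(ctab))
      }
    }
  }
  n <- nrow(r)
  structure(
    list(totals = totals,
         class_totals = class_totals,
         relative_counts = totals / n,
         grand_total = sum(totals),
         grand_relative = sum(totals) / n,
         n_mirnas = n,
         min_repeats = min_repeats,
         tracts = tracts),
    class = "ssr_summary"
  )
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("SSR summary over %d miRNAs (min %d complete repeats)\n",
              x$n_mirnas, x$min_repeats))
  labels <- c("mono", "di", "tri", "tetra", "penta")[seq_along(x$totals)]
  for (i in seq_along(x$totals)) {
    cat(sprintf("  %-5s: %d (%.2f)\n", labels[i], x$totals[i],
                round_half_up(x$relative_counts[i], 2)))
  }
  cat(sprintf("  total: %d (%.2f)\n", x$grand_total,
              round_half_up(x$grand_relative, 2)))
  invisible(x)
}

#' SSR relative count
#'
#' The library-level normalization used for repeat censuses: the number of
#' repeat tracts divided by the number of miRNAs, reported to two decimals
#' half away from zero (e.g. 2326 tracts over 2042 miRNAs gives 1.14).
#'
#' @param n_tracts Total number of repeat tracts.
#' @param n_mirnas Number of miRNAs in the analyzed group.
#' @param digits Decimals in the reported value (default 2).
#' @return The rounded relative count.
#' @export
#' @examples
#' ssr_relative_count(2326, 2042)  # 1.14
ssr_relative_count <- function(n_tracts, n_mirnas, digits = 2) {
  stopifnot(n_mirnas > 0)
  round_half_up(n_tracts / n_mirnas, digits)
}

#' Longest mononucleotide run of a base
#'
#' Maximum run length of a single base over all records, together with the
#' ids achieving it. Runs of any length count (not only those passing the
#' SSR `min_repeats` floor), so maxima of 1 or 2 are well-defined on
#' degenerate libraries.
#'
#' @param library A non-empty [mirna_library()].
#' @param base One of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return A list with `length` (integer, 0 if the base never occurs) and
#'   `ids` (character vector of records achieving the maximum; empty when
#'   `length` is 0).
#' @export
longest_mono_run <- function(library, base) {
  stopifnot(inherits(library, "mirna_library"))
  if (nrow(library$records) == 0L) {
    stop("longest run is undefined for an empty library", call. = FALSE)
  }
  base <- normalize_sequence(base)
  if (!base %in% RNA_BASES) {
    stop(sprintf("base must be one of A, C, G, U (got '%s')", base),
         call. = FALSE)
  }
  per_record <- vapply(seq_chars(library$records$sequence), function(cc) {
    rl <- rle(cc)
    runs <- rl$lengths[rl$values == base]
    if (length(runs)) max(runs) else 0L
  }, integer(1))
  best <- max(per_record)
  list(length = best,
       ids = if (best > 0L) library$records$id[per_record == best]
             else character(0))
}
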