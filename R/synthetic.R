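# Seeded synthetic miRNA library generation with plantable features
# (motifs, SSR tracts, hairpins, terminal bases) and exact ground-truth
# bookkeeping, so every analysis stage can be tested end-to-end without a
# download.
#
# Background positions are i.i.d. from the configured base frequencies;
# around planted features a small amount of local resampling (flank bases
# that would extend a planted tract or stem) and whole-record rejection
# (records that pick up chance occurrences of a planted feature type) keep
# the ground truth exact. This is a slight, documented departure from a
# pure i.i.d. background.

#' Default synthetic length distribution
#'
#' Lengths 16-27 nt with mode 22 (probability 0.47), 21 at 0.12, 23 at
#' 0.14, and the remaining mass spread uniformly over the other nine
#' lengths — a qualitative mimic of the mature human miRNA length profile.
#'
#' @return Named numeric vector of probabilities (names = lengths).
#' @export
default_length_distribution <- function() {
  lens <- 16:27
  p <- stats::setNames(rep(0.27 / 9, length(lens)), lens)
  p["21"] <- 0.12
  p["22"] <- 0.47
  p["23"] <- 0.14
  p
}

#' Planted-feature directives
#'
#' Constructors for the feature directives accepted by [synthetic_spec()].
#' Each directive plants its feature in `round(fraction * n_sequences)`
#' records, chosen at random; `fraction = 1` plants in every record.
#'
#' * `feature_motif()`: an exact motif occurrence at a random position.
#' * `feature_ssr()`: a tract of `repeat_count` complete copies of `unit`
#'   (primitive, 1-5 nt), with flanks guaranteed not to extend it, so the
#'   planted boundaries are exact maximal-tract boundaries. The repeated
#'   tract itself must not contain a qualifying repeat of another unit
#'   length.
#' * `feature_hairpin()`: a stem-loop of `stem_length` Watson-Crick pairs
#'   enclosing `loop_seq`, with the given closing pair (5' base, 3' base)
#'   innermost and flanks guaranteed not to extend the stem.
#' * `feature_terminal()`: a fixed base at the 5' or 3' terminus.
#'
#' @param motif,unit,loop_seq Sequence strings over \{A,C,G,U\}.
#' @param fraction Fraction of records to plant in, in \[0,1\].
#' @param repeat_count Number of complete unit copies (>= 3 to be
#'   detectable under the default census rule).
#' @param stem_length Stem length in base pairs.
#' @param closing_pair Length-2 character vector, 5' then 3' base of the
#'   innermost pair.
#' @param base,end Terminal base and which end (`"five_prime"` /
#'   `"three_prime"`).
#' @return A `planted_feature` directive list.
#' @name planted_features
NULL

#' @rdname planted_features
#' @export
feature_motif <- function(motif, fraction) {
  motif <- normalize_sequence(motif)
  validate_motif(motif)
  stopifnot(fraction >= 0, fraction <= 1)
  structure(list(type = "motif", motif = motif, fraction = fraction),
            class = "planted_feature")
}

#' @rdname planted_features
#' @export
feature_ssr <- function(unit, repeat_count, fraction) {
  unit <- normalize_sequence(unit)
  validate_motif(unit, "unit")
  stopifnot(nchar(unit) <= 5L, repeat_count >= 2L,
            fraction >= 0, fraction <= 1)
  if (!is_primitive_unit(unit)) {
    stop(sprintf("unit '%s' is not primitive", unit), call. = FALSE)
  }
  tract <- strrep(unit, repeat_count)
  self_scan <- find_ssrs(tract, min_repeats = min(3L, repeat_count))
  extra <- self_scan[self_scan$unit_length != nchar(unit), , drop = FALSE]
  if (nrow(extra)) {
    stop(sprintf(
      "planted tract (%s)%d contains a qualifying repeat of another unit length (%s)",
      unit, repeat_count, extra$unit[1]), call. = FALSE)
  }
  structure(list(type = "ssr", unit = unit,
                 repeat_count = as.integer(repeat_count),
                 fraction = fraction),
            class = "planted_feature")
}

#' @rdname planted_features
#' @export
feature_hairpin <- function(stem_length, loop_seq, closing_pair = c("C", "G"),
                            fraction = 1) {
  loop_seq <- normalize_sequence(loop_seq)
  validate_motif(loop_seq, "loop_seq")
  closing_pair <- normalize_sequence(closing_pair)
  stopifnot(stem_length >= 1L, nchar(loop_seq) >= 3L,
            length(closing_pair) == 2L,
            fraction >= 0, fraction <= 1)
  if (!pair_ok(closing_pair[1], closing_pair[2], allow_wobble = TRUE)) {
    stop("closing_pair bases must form a valid pair", call. = FALSE)
  }
  structure(list(type = "hairpin", stem_length = as.integer(stem_length),
                 loop_seq = loop_seq, closing_pair = closing_pair,
                 fraction = fraction),
            class = "planted_feature")
}

#' @rdname planted_features
#' @export
feature_terminal <- function(base, end = c("five_prime", "three_prime"),
                             fraction = 1) {
  base <- normalize_sequence(base)
  end <- match.arg(end)
  stopifnot(base %in% RNA_BASES, fraction >= 0, fraction <= 1)
  structure(list(type = "terminal", base = base, end = end,
                 fraction = fraction),
            class = "planted_feature")
}

#' Specification of a synthetic miRNA library
#'
#' @param n_sequences Number of records to generate.
#' @param length_distribution Named probability vector over lengths
#'   (default [default_length_distribution()]).
#' @param base_frequencies Named probabilities for A/C/G/U (default the
#'   pooled composition of the mature human set: A 0.23, C 0.22, G 0.29,
#'   U 0.26).
#' @param planted_features List of [planted_features] directives.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec and seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_sequences,
                           length_distribution = default_length_distribution(),
                           base_frequencies = c(A = 0.23, C = 0.22,
                                                G = 0.29, U = 0.26),
                           planted_features = list(),
                           seed = 1L) {
  stopifnot(n_sequences >= 0)
  if (is.null(names(length_distribution)) ||
      any(is.na(as.integer(names(length_distribution))))) {
    stop("length_distribution must be named by integer lengths",
         call. = FALSE)
  }
  if (abs(sum(length_distribution) - 1) > 1e-9) {
    stop("length_distribution probabilities must sum to 1", call. = FALSE)
  }
  if (!setequal(names(base_frequencies), RNA_BASES) ||
      abs(sum(base_frequencies) - 1) > 1e-9) {
    stop("base_frequencies must be named A/C/G/U and sum to 1",
         call. = FALSE)
  }
  for (f in planted_features) {
    if (!inherits(f, "planted_feature")) {
      stop("planted_features must be built with the feature_*() constructors",
           call. = FALSE)
    }
  }
  structure(
    list(n_sequences = as.integer(n_sequences),
         length_distribution = length_distribution,
         base_frequencies = base_frequencies[RNA_BASES],
         planted_features = planted_features,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Minimum record length a feature insert needs.
feature_width <- function(f) {
  switch(f$type,
         motif = nchar(f$motif),
         ssr = nchar(f$unit) * f$repeat_count,
         hairpin = 2L * f$stem_length + nchar(f$loop_seq),
         terminal = 1L)
}

# Draw one base excluding `forbidden`, with the background frequencies
# renormalized over the remaining alphabet.
draw_base_excluding <- function(freqs, forbidden) {
  allowed <- setdiff(RNA_BASES, forbidden)
  p <- freqs[allowed]
  sample(allowed, 1L, prob = p / sum(p))
}

# Build the insert string and relative pair layout for a hairpin feature.
build_hairpin_insert <- function(f, freqs) {
  s <- f$stem_length
  wc_partner <- c(A = "U", U = "A", G = "C", C = "G")
  left <- character(s)
  left[s] <- f$closing_pair[1]
  if (s > 1L) {
    left[seq_len(s - 1L)] <- sample(RNA_BASES, s - 1L, replace = TRUE,
                                    prob = freqs)
  }
  right_inner_to_outer <- c(f$closing_pair[2],
                            if (s > 1L) wc_partner[left[(s - 1L):1L]])
  insert <- paste0(paste(left, collapse = ""), f$loop_seq,
                   paste(right_inner_to_outer, collapse = ""))
  w <- nchar(insert)
  list(insert = insert,
       loop_start_rel = s + 1L,
       loop_end_rel = s + nchar(f$loop_seq),
       width = w)
}

# Attempt to place feature intervals disjointly within a record of length
# `len`; returns a list of (start, width) or NULL on failure.
place_intervals <- function(widths, reserved, len) {
  placed <- reserved  # list of c(start, end) already occupied
  out <- vector("list", length(widths))
  for (k in seq_along(widths)) {
    w <- widths[k]
    ok <- FALSE
    for (try in seq_len(50L)) {
      if (len - w + 1L < 1L) return(NULL)
      st <- sample.int(len - w + 1L, 1L)
      en <- st + w - 1L
      clash <- any(vapply(placed, function(iv) st <= iv[2] && en >= iv[1],
                          logical(1)))
      if (!clash) {
        placed[[length(placed) + 1L]] <- c(st, en)
        out[[k]] <- c(start = st, end = en)
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
  }
  out
}

#' Generate a synthetic miRNA library with ground truth
#'
#' Deterministic given the spec's seed. Each planted-feature directive is
#' applied to exactly `round(fraction * n)` records. After planting, every
#' record is certified against the directive set: every planted motif
#' occurrence and SSR tract is present with exact (maximal) boundaries,
#' planted hairpins are recoverable with exact loop boundaries and stem
#' length, and background regions are free of chance occurrences of the
#' planted feature types (a finding inside another planted insert — e.g. a
#' mono-A run inside a planted GAAA tetraloop — is a legitimate consequence
#' of that insert and is recorded, not rejected). Records failing
#' certification are resampled (up to 500 attempts each).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `library` (a [mirna_library()], source
#'   `"synthetic"`) and `truth` — per-record ground truth (`motifs`,
#'   `ssrs`, `hairpins`, `terminal`, each with exact 1-based coordinates)
#'   plus `feature_ids`, the record ids assigned to each directive.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_sequences
  empty_truth <- list(records = stats::setNames(list(), character(0)),
                      feature_ids = list())
  if (n == 0L) {
    return(list(library = mirna_library(character(0), character(0),
                                        source = "synthetic"),
                truth = empty_truth))
  }
  with_seed(spec$seed, {
    freqs <- spec$base_frequencies
    lens_support <- as.integer(names(spec$length_distribution))
    lengths <- lens_support[sample.int(length(lens_support), n,
                                       replace = TRUE,
                                       prob = spec$length_distribution)]
    feats <- spec$planted_features
    # directive -> record assignment (exact counts)
    assignment <- vector("list", length(feats))
    for (k in seq_along(feats)) {
      cnt <- round(feats[[k]]$fraction * n)
      assignment[[k]] <- if (cnt > 0L) sort(sample.int(n, cnt)) else integer(0)
    }
    motif_set <- unique(vapply(
      Filter(function(f) f$type == "motif", feats),
      function(f) f$motif, character(1)))
    any_ssr <- any(vapply(feats, function(f) f$type == "ssr", logical(1)))

    ids <- sprintf("syn-%05d", seq_len(n))
    sequences <- character(n)
    truth_records <- vector("list", n)
    names(truth_records) <- ids

    for (i in seq_len(n)) {
      fidx <- which(vapply(assignment, function(a) i %in% a, logical(1)))
      my_feats <- feats[fidx]
      insert_feats <- Filter(function(f) f$type %in% c("motif", "ssr", "hairpin"),
                             my_feats)
      term_feats <- Filter(function(f) f$type == "terminal", my_feats)
      need <- sum(vapply(insert_feats, feature_width, integer(1)))
      len <- lengths[i]
      if (len < need) {
        fits <- lens_support[lens_support >= need]
        if (!length(fits)) {
          stop(sprintf(
            "infeasible spec: planted features need %d nt but the longest length is %d",
            need, max(lens_support)), call. = FALSE)
        }
        p <- spec$length_distribution[as.character(fits)]
        len <- fits[sample.int(length(fits), 1L, prob = p / sum(p))]
        lengths[i] <- len
      }

      rec <- NULL
      for (attempt in seq_len(500L)) {
        cc <- sample(RNA_BASES, len, replace = TRUE, prob = freqs)
        # reserve terminal positions so inserts cannot cover them
        reserved <- lapply(term_feats, function(f) {
          pos <- if (f$end == "five_prime") 1L else len
          c(pos, pos)
        })
        truth_i <- list(motifs = NULL, ssrs = NULL,
                        hairpins = list(), terminal = NULL,
                        insert_intervals = NULL)
        prepared <- lapply(insert_feats, function(f) {
          if (f$type == "hairpin") build_hairpin_insert(f, freqs) else NULL
        })
        widths <- vapply(seq_along(insert_feats), function(k) {
          if (insert_feats[[k]]$type == "hairpin") prepared[[k]]$width
          else feature_width(insert_feats[[k]])
        }, integer(1))
        spots <- place_intervals(widths, reserved, len)
        if (is.null(spots) && length(widths)) next
        ok <- TRUE
        for (k in seq_along(insert_feats)) {
          f <- insert_feats[[k]]
          st <- spots[[k]]["start"]; en <- spots[[k]]["end"]
          truth_i$insert_intervals <- rbind(truth_i$insert_intervals,
            data.frame(type = f$type, start = st, end = en,
                       row.names = NULL))
          if (f$type == "motif") {
            cc[st:en] <- seq_chars(f$motif)[[1]]
            truth_i$motifs <- rbind(truth_i$motifs, data.frame(
              motif = f$motif, start = st, end = en))
          } else if (f$type == "ssr") {
            ku <- nchar(f$unit)
            cc[st:en] <- seq_chars(strrep(f$unit, f$repeat_count))[[1]]
            u <- seq_chars(f$unit)[[1]]
            # flanks must not extend the tract (as complete units or a
            # phase-shifted rotation through the adjacent base)
            if (st > 1L && cc[st - 1L] == u[ku]) {
              cc[st - 1L] <- draw_base_excluding(freqs, u[ku])
            }
            if (en < len && cc[en + 1L] == u[1L]) {
              cc[en + 1L] <- draw_base_excluding(freqs, u[1L])
            }
            truth_i$ssrs <- rbind(truth_i$ssrs, data.frame(
              unit = f$unit, repeat_count = f$repeat_count,
              start = st, end = en))
          } else if (f$type == "hairpin") {
            hp <- prepared[[k]]
            cc[st:en] <- seq_chars(hp$insert)[[1]]
            # prevent outward stem extension past the planted stem
            if (st > 1L && en < len && pair_ok(cc[st - 1L], cc[en + 1L])) {
              partners <- RNA_BASES[pair_ok(cc[st - 1L], RNA_BASES)]
              cc[en + 1L] <- draw_base_excluding(freqs, partners)
            }
            s <- f$stem_length
            truth_i$hairpins[[length(truth_i$hairpins) + 1L]] <- list(
              stem_length = s,
              loop_start = st + hp$loop_start_rel - 1L,
              loop_end = st + hp$loop_end_rel - 1L,
              loop_seq = f$loop_seq,
              closing_pair = f$closing_pair,
              pairs = cbind(i = st:(st + s - 1L),
                            j = en:(en - s + 1L)))
          }
        }
        for (f in term_feats) {
          pos <- if (f$end == "five_prime") 1L else len
          cc[pos] <- f$base
          truth_i$terminal <- rbind(truth_i$terminal, data.frame(
            base = f$base, end = f$end))
        }
        seq_i <- paste(cc, collapse = "")

        # --- certification against the directive set ---
        # Chance findings are rejected only in background regions: a repeat
        # or motif occurring inside another planted insert (e.g. an (A)3 run
        # inside a planted GAAA tetraloop) is a legitimate consequence of
        # that feature, not a false positive.
        ivs <- truth_i$insert_intervals
        overlaps_insert <- function(st, en, exclude_type = NULL) {
          if (is.null(ivs)) return(FALSE)
          keep <- if (is.null(exclude_type)) rep(TRUE, nrow(ivs)) else
            ivs$type != exclude_type
          any(keep & st <= ivs$end & en >= ivs$start)
        }
        for (m in motif_set) {
          expected <- if (is.null(truth_i$motifs)) integer(0) else
            truth_i$motifs$start[truth_i$motifs$motif == m]
          found <- scan_motif(seq_i, m, overlapping = TRUE)$start
          if (!all(expected %in% found)) { ok <- FALSE; break }
          extras <- setdiff(found, expected)
          w <- nchar(m)
          in_insert <- vapply(extras, function(st)
            overlaps_insert(st, st + w - 1L, exclude_type = "motif"),
            logical(1))
          if (!all(in_insert)) { ok <- FALSE; break }
        }
        if (ok && any_ssr) {
          found <- find_ssrs(seq_i, min_repeats = 3L, max_unit = 5L)
          exp_df <- truth_i$ssrs
          exp_key <- if (is.null(exp_df)) character(0) else
            sprintf("%s:%d-%d", exp_df$unit, exp_df$start, exp_df$end)
          got_key <- sprintf("%s:%d-%d", found$unit, found$start, found$end)
          if (!all(exp_key %in% got_key)) ok <- FALSE
          if (ok) {
            extras <- found[!got_key %in% exp_key, , drop = FALSE]
            in_insert <- vapply(seq_len(nrow(extras)), function(r)
              overlaps_insert(extras$start[r], extras$end[r],
                              exclude_type = "ssr"),
              logical(1))
            if (!all(in_insert)) ok <- FALSE
          }
        }
        if (ok && length(truth_i$hairpins)) {
          for (h in truth_i$hairpins) {
            ll <- nchar(h$loop_seq)
            hps <- enumerate_hairpins(seq_i, min_stem = h$stem_length,
                                      loop_min = max(3L, ll), loop_max = ll)
            hit <- Filter(function(x) {
              x$loop_start == h$loop_start && x$loop_end == h$loop_end &&
                x$stem_length == h$stem_length
            }, hps)
            if (!length(hit)) { ok <- FALSE; break }
          }
        }
        if (ok) {
          rec <- list(sequence = seq_i, truth = truth_i)
          break
        }
      }
      if (is.null(rec)) {
        stop(sprintf(
          "could not generate record %d satisfying the planted-feature certification", i),
          call. = FALSE)
      }
      sequences[i] <- rec$sequence
      truth_records[[i]] <- rec$truth
    }

    feature_ids <- lapply(seq_along(feats), function(k) {
      list(feature = feats[[k]], ids = ids[assignment[[k]]])
    })
    list(
      library = mirna_library(ids, sequences, source = "synthetic"),
      truth = list(records = truth_records, feature_ids = feature_ids)
    )
  })
}
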