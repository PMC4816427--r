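# Independent brute-force oracles and small generators used across the
# suite. Each oracle re-derives the expected result by exhaustive
# enumeration, never by calling the implementation path it checks.

random_rna <- function(n, min_len = 10, max_len = 30,
                       bases = c("A", "C", "G", "U"), prob = NULL) {
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste(sample(bases, len, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

# All occurrences of `motif` by testing every substring.
oracle_motif_starts <- function(sequence, motif) {
  n <- nchar(sequence)
  m <- nchar(motif)
  if (m > n) return(integer(0))
  which(vapply(seq_len(n - m + 1), function(i) {
    substr(sequence, i, i + m - 1) == motif
  }, logical(1)))
}

# Maximal alternating-GU runs by extending every admissible start.
oracle_gu_tracts <- function(sequence, min_length = 5) {
  cc <- strsplit(sequence, "")[[1]]
  n <- length(cc)
  is_gu <- cc %in% c("G", "U")
  alt_run_from <- function(i) {
    j <- i
    while (j < n && is_gu[j + 1] && cc[j + 1] != cc[j]) j <- j + 1
    j
  }
  out <- NULL
  for (i in seq_len(n)) {
    if (!is_gu[i]) next
    left_max <- i == 1 || !is_gu[i - 1] || cc[i - 1] == cc[i]
    if (!left_max) next
    j <- alt_run_from(i)
    if (j - i + 1 >= min_length) {
      out <- rbind(out, data.frame(start = i, end = j))
    }
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0)) else out
}

# Brute-force SSR oracle: enumerate every (unit length, phase) maximal
# primitive tract with >= min_repeats complete repeats, then apply the
# leftmost-greedy non-overlapping selection within each unit length.
oracle_ssrs <- function(sequence, min_repeats = 3, max_unit = 5) {
  n <- nchar(sequence)
  primitive <- function(u) {
    k <- nchar(u)
    if (k == 1) return(TRUE)
    !any(vapply(seq_len(k - 1), function(d) {
      k %% d == 0 && u == strrep(substr(u, 1, d), k / d)
    }, logical(1)))
  }
  out <- NULL
  for (k in seq_len(max_unit)) {
    cands <- NULL
    for (i in seq_len(max(0, n - k * min_repeats + 1))) {
      unit <- substr(sequence, i, i + k - 1)
      if (!primitive(unit)) next
      r <- 1
      while (i + (r + 1) * k - 1 <= n &&
             substr(sequence, i + r * k, i + (r + 1) * k - 1) == unit) {
        r <- r + 1
      }
      if (r < min_repeats) next
      left_max <- i - k < 1 || substr(sequence, i - k, i - 1) != unit
      if (!left_max) next
      cands <- rbind(cands, data.frame(
        unit = unit, unit_length = k, repeat_count = r,
        start = i, end = i + r * k - 1, stringsAsFactors = FALSE))
    }
    if (is.null(cands)) next
    cands <- cands[order(cands$start), , drop = FALSE]
    taken_end <- 0
    for (r in seq_len(nrow(cands))) {
      if (cands$start[r] > taken_end) {
        out <- rbind(out, cands[r, , drop = FALSE])
        taken_end <- cands$end[r]
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(unit = character(0), unit_length = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$unit_length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force hairpin oracle: test every (loop placement, stem length)
# combination directly against the pairing rule and maximality.
oracle_hairpins <- function(sequence, min_stem = 3, loop_min = 3,
                            loop_max = 8, allow_wobble = TRUE) {
  cc <- strsplit(sequence, "")[[1]]
  n <- length(cc)
  ok_pair <- function(a, b) {
    wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
          (a == "G" && b == "C") || (a == "C" && b == "G")
    wb <- (a == "G" && b == "U") || (a == "U" && b == "G")
    wc || (allow_wobble && wb)
  }
  out <- NULL
  for (ls in 2:max(2, n)) {
    for (le in ls:min(n - 1, ls + loop_max - 1)) {
      loop_len <- le - ls + 1
      if (loop_len < loop_min || ls < 2 || le > n - 1) next
      # largest s with all pairs valid
      s <- 0
      while (ls - s - 1 >= 1 && le + s + 1 <= n &&
             ok_pair(cc[ls - s - 1], cc[le + s + 1])) {
        s <- s + 1
      }
      if (s >= min_stem) {
        out <- rbind(out, data.frame(
          stem_length = s, loop_start = ls, loop_end = le,
          loop_seq = substr(sequence, ls, le), stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(stem_length = integer(0), loop_start = integer(0),
                      loop_end = integer(0), loop_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  loop_len <- out$loop_end - out$loop_start + 1
  out <- out[order(-out$stem_length, loop_len, out$loop_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

hairpin_df <- function(hps) {
  if (!length(hps)) {
    return(data.frame(stem_length = integer(0), loop_start = integer(0),
                      loop_end = integer(0), loop_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(hps, function(h) {
    data.frame(stem_length = h$stem_length, loop_start = h$loop_start,
               loop_end = h$loop_end, loop_seq = h$loop_seq,
               stringsAsFactors = FALSE)
  }))
}
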