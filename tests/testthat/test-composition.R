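# Base content, positional occupancy, terminal bases and
# purine/pyrimidine classification.

test_that("pooled base content matches a per-character tally oracle", {
  expect_equal(unname(base_content(mirna_library("x", "AAAA"))$fractions),
               c(1, 0, 0, 0))
  # the published UGUGU-table sequences, pooled
  lib <- fixture_library("iim")
  prof <- base_content(lib)
  chars <- unlist(strsplit(lib$records$sequence, ""))
  oracle <- table(factor(chars, levels = c("A", "C", "G", "U")))
  expect_equal(unname(prof$counts), as.integer(oracle))
  expect_equal(prof$n_nucleotides, sum(nchar(lib$records$sequence)))
  expect_equal(sum(prof$fractions), 1, tolerance = 1e-9)
  expect_error(base_content(mirna_library(character(0), character(0))),
               "empty")
})

test_that("positional occupancy matches a brute-force tally at both anchors", {
  one <- positional_frequency(mirna_library("x", "GAC"), "five_prime")
  expect_equal(unclass(one)[, c("G", "A", "C")],
               matrix(diag(3), 3, 3, dimnames = list(1:3, c("G", "A", "C"))),
               ignore_attr = TRUE)
  set.seed(21)
  seqs <- random_rna(10, 8, 20)
  lib <- mirna_library(sprintf("r%02d", 1:10), seqs)
  for (anchor in c("five_prime", "three_prime")) {
    pfm <- positional_frequency(lib, anchor)
    maxlen <- max(nchar(seqs))
    for (p in seq_len(maxlen)) {
      at_p <- vapply(seqs, function(s) {
        n <- nchar(s)
        if (n < p) return(NA_character_)
        if (anchor == "five_prime") substr(s, p, p)
        else substr(s, n - p + 1, n - p + 1)
      }, character(1))
      for (b in c("A", "C", "G", "U")) {
        expect_equal(unclass(pfm)[p, b], sum(at_p == b, na.rm = TRUE))
      }
      expect_equal(attr(pfm, "n_covering")[p], sum(!is.na(at_p)))
    }
    # coverage is non-increasing in position
    expect_true(all(diff(attr(pfm, "n_covering")) <= 0))
  }
})

test_that("both anchors pool to the same base totals as base_content", {
  lib <- fixture_library("gu_rich")
  totals <- base_content(lib)$counts
  five <- positional_frequency(lib, "five_prime")
  three <- positional_frequency(lib, "three_prime")
  expect_equal(colSums(unclass(five)), as.numeric(totals),
               ignore_attr = TRUE)
  expect_equal(colSums(unclass(three)), as.numeric(totals),
               ignore_attr = TRUE)
})

test_that("reversing every sequence swaps the two anchor matrices exactly", {
  set.seed(22)
  seqs <- random_rna(15, 10, 27)
  lib <- mirna_library(sprintf("r%02d", 1:15), seqs)
  rev_seqs <- vapply(strsplit(seqs, ""), function(cc) {
    paste(rev(cc), collapse = "")
  }, character(1))
  rlib <- mirna_library(sprintf("r%02d", 1:15), rev_seqs)
  expect_equal(unclass(positional_frequency(lib, "five_prime")),
               unclass(positional_frequency(rlib, "three_prime")),
               ignore_attr = TRUE)
  expect_equal(unclass(positional_frequency(lib, "three_prime")),
               unclass(positional_frequency(rlib, "five_prime")),
               ignore_attr = TRUE)
})

test_that("terminal-base table matches first/last-character tallies", {
  lib <- fixture_library("gu_rich")
  tb <- terminal_bases(lib)
  firsts <- substr(lib$records$sequence, 1, 1)
  lasts <- substr(lib$records$sequence, lib$records$length,
                  lib$records$length)
  for (b in c("A", "C", "G", "U")) {
    expect_equal(sum(tb$count[tb$end == "five_prime" & tb$base == b]),
                 sum(firsts == b))
    expect_equal(sum(tb$count[tb$end == "three_prime" & tb$base == b]),
                 sum(lasts == b))
  }
  expect_equal(sum(tb$count), 2L * nrow(lib$records))
  # a library built to start with U everywhere
  ulib <- mirna_library(c("a", "b"), c("UAAAC", "UGGGG"))
  utb <- terminal_bases(ulib)
  expect_equal(sum(utb$count[utb$end == "five_prime" & utb$base == "U"]), 2L)
})

test_that("purine/pyrimidine calls reproduce all published table rows", {
  tb <- pp_rich_mirnas()
  pp <- classify_pp(mirna_library(tb$id, tb$sequence))
  expect_equal(pp$richness_pct, tb$printed_pct)
  expect_equal(pp$call, tb$group)
  expect_true(all(pp$highly_rich))
  expect_equal(pp$purine_fraction + pp$pyrimidine_fraction, rep(1, 11),
               tolerance = 1e-9)
})

test_that("the hsa-miR-4271 printed-length discrepancy is flagged", {
  tb <- pp_rich_mirnas()
  expect_equal(tb$id[tb$length_discrepancy], "hsa-miR-4271")
  expect_equal(nchar(tb$sequence[tb$id == "hsa-miR-4271"]), 19L)
  expect_equal(tb$printed_length[tb$id == "hsa-miR-4271"], 22)
})

test_that("richness threshold is strict and configurable", {
  even <- classify_pp("GCGC")
  expect_equal(even$call, "neither")
  expect_equal(even$purine_fraction, 0.5)
  # exactly at the threshold is not rich (strict >)
  at_thr <- classify_pp("AAAAAAACCC", threshold = 0.7)
  expect_equal(at_thr$purine_fraction, 0.7)
  expect_equal(at_thr$call, "neither")
  expect_equal(classify_pp("AAAAAAACCC", threshold = 0.69)$call,
               "purine_rich")
})

test_that("percentages round half away from zero", {
  expect_equal(round_half_up(90.5), 91)
  expect_equal(round_half_up(-90.5), -91)
  expect_equal(round_half_up(1.139, 2), 1.14)
  # 19/21 = 90.476... -> 90, as in the published pyrimidine rows
  expect_equal(round_half_up(100 * 19 / 21), 90)
})
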