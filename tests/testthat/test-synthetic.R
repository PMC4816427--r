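# Synthetic library generation: determinism, planted-feature recovery and
# background statistics.

test_that("generation is deterministic and leaves the caller's RNG alone", {
  spec <- synthetic_spec(30, planted_features = list(
    feature_motif("UGUGU", 0.2)), seed = 101)
  g1 <- generate_library(spec)
  set.seed(999)
  drawn_before <- runif(1)
  set.seed(999)
  g2 <- generate_library(spec)
  drawn_after <- runif(1)
  expect_equal(g1$library$records, g2$library$records)
  expect_equal(drawn_before, drawn_after)  # RNG state restored
  # byte-identical FASTA on re-generation
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_mirna_fasta(g1$library, f1)
  write_mirna_fasta(g2$library, f2)
  expect_equal(readLines(f1), readLines(f2))
  # a different seed changes the library
  g3 <- generate_library(synthetic_spec(30, planted_features = list(
    feature_motif("UGUGU", 0.2)), seed = 102))
  expect_false(identical(g1$library$records$sequence,
                         g3$library$records$sequence))
})

test_that("n = 0 yields an empty library and empty truth", {
  g <- generate_library(synthetic_spec(0, seed = 1))
  expect_equal(nrow(g$library$records), 0L)
  expect_length(g$truth$records, 0L)
})

test_that("planted motifs land in exactly the designated records", {
  spec <- synthetic_spec(100, planted_features = list(
    feature_motif("UGUGU", 0.3)), seed = 42)
  g <- generate_library(spec)
  planted_ids <- g$truth$feature_ids[[1]]$ids
  expect_length(planted_ids, 30L)
  census <- find_iim(g$library)
  expect_setequal(census$id, planted_ids)
  # planted coordinates index the motif exactly
  for (id in planted_ids) {
    t <- g$truth$records[[id]]
    s <- g$library$records$sequence[g$library$records$id == id]
    expect_equal(substring(s, t$motifs$start, t$motifs$end), t$motifs$motif)
  }
})

test_that("planted SSR tracts are recovered with exact maximal boundaries", {
  spec <- synthetic_spec(60, planted_features = list(
    feature_ssr("GU", 4, 0.4),
    feature_ssr("A", 4, 0.3)), seed = 43)
  g <- generate_library(spec)
  for (id in g$library$records$id) {
    t <- g$truth$records[[id]]
    s <- g$library$records$sequence[g$library$records$id == id]
    found <- find_ssrs(s)
    if (is.null(t$ssrs)) {
      # certified feature-free records: no tract at all
      expect_equal(nrow(found), 0L)
    } else {
      for (r in seq_len(nrow(t$ssrs))) {
        hit <- found[found$unit == t$ssrs$unit[r] &
                     found$start == t$ssrs$start[r] &
                     found$end == t$ssrs$end[r], ]
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$repeat_count, t$ssrs$repeat_count[r])
      }
    }
  }
})

test_that("planted hairpins are recovered with exact loop boundaries", {
  spec <- synthetic_spec(40, planted_features = list(
    feature_hairpin(4, "UUCG", c("C", "G"), 0.5)), seed = 44)
  g <- generate_library(spec)
  planted_ids <- g$truth$feature_ids[[1]]$ids
  expect_length(planted_ids, 20L)
  for (id in planted_ids) {
    t <- g$truth$records[[id]]
    s <- g$library$records$sequence[g$library$records$id == id]
    for (h in t$hairpins) {
      hps <- enumerate_hairpins(s, min_stem = h$stem_length,
                                loop_min = 4, loop_max = 4)
      match <- Filter(function(x) {
        x$loop_start == h$loop_start && x$loop_end == h$loop_end &&
          x$stem_length == h$stem_length && x$loop_seq == h$loop_seq
      }, hps)
      expect_length(match, 1L)
      expect_equal(match[[1]]$closing_pair, h$closing_pair)
    }
  }
})

test_that("terminal-base directives fix the designated terminus", {
  spec <- synthetic_spec(25, planted_features = list(
    feature_terminal("U", "five_prime", 1)), seed = 45)
  g <- generate_library(spec)
  expect_true(all(startsWith(g$library$records$sequence, "U")))
  tb <- terminal_bases(g$library)
  expect_equal(sum(tb$count[tb$end == "five_prime" & tb$base == "U"]), 25L)
})

test_that("background base frequencies match the spec within 3 standard errors", {
  freqs <- c(A = 0.23, C = 0.22, G = 0.29, U = 0.26)
  # ~1e5 nt of pure background
  spec <- synthetic_spec(4600, base_frequencies = freqs, seed = 46)
  g <- generate_library(spec)
  chars <- unlist(strsplit(g$library$records$sequence, ""))
  n <- length(chars)
  expect_gte(n, 9e4)
  for (b in names(freqs)) {
    p <- freqs[[b]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(chars == b) - p), 3 * se)
  }
})

test_that("length distribution and overrides behave as specified", {
  spec <- synthetic_spec(100, length_distribution = c("20" = 0.3, "22" = 0.7),
                         seed = 47)
  g <- generate_library(spec)
  lens <- g$library$records$length
  expect_true(all(lens %in% c(20L, 22L)))
  ld <- length_distribution(g$library)
  # the distribution object mirrors a direct tally of the generated records
  expect_equal(unname(ld$counts[as.character(sort(unique(lens)))]),
               as.integer(table(lens)))
  expect_equal(sum(ld$counts), 100L)
})

test_that("infeasible and malformed specs are rejected", {
  expect_error(synthetic_spec(5, length_distribution = c("20" = 0.5)),
               "sum to 1")
  expect_error(synthetic_spec(5, base_frequencies = c(A = 1)), "A/C/G/U")
  expect_error(feature_ssr("GUGU", 3, 0.5), "primitive")
  expect_error(feature_ssr("GGGA", 3, 0.5), "another unit length")
  expect_error(feature_hairpin(3, "GAAA", c("A", "G")), "valid pair")
  # a feature that cannot fit in any admissible length
  spec <- synthetic_spec(3, length_distribution = c("16" = 1),
                         planted_features = list(
                           feature_hairpin(8, "GAAAAAAA", c("C", "G"), 1)),
                         seed = 48)
  expect_error(generate_library(spec), "infeasible")
})
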