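# Stem-loop enumeration, tetraloop classification, stability score and
# dot-bracket output.

test_that("a constructed stem-loop is found with exact pairs and loop", {
  hps <- enumerate_hairpins("GGGAAAACCC")
  expect_length(hps, 1L)
  hp <- hps[[1]]
  expect_equal(hp$stem_length, 3L)
  expect_equal(hp$pairs, cbind(i = 1:3, j = 10:8))
  expect_equal(hp$loop_seq, "AAAA")
  expect_equal(c(hp$loop_start, hp$loop_end), c(4L, 7L))
  expect_equal(hp$closing_pair, c("G", "C"))
  expect_length(enumerate_hairpins("AAAAAA"), 0L)
  expect_null(best_hairpin("ACGU"))
})

test_that("best hairpin prefers the longer stem", {
  # two disjoint candidates with stems 4 and 3
  s <- "GGGGAAAACCCCAUGGGAAACCC"
  best <- best_hairpin(s)
  expect_equal(best$stem_length, 4L)
  expect_equal(best$loop_seq, "AAAA")
  oracle <- oracle_hairpins(s)
  expect_equal(best$stem_length, oracle$stem_length[1])
  expect_equal(best$loop_start, oracle$loop_start[1])
})

test_that("enumeration equals the exhaustive oracle on published and random input", {
  # a published GU-rich sequence
  s <- "UGAGGUAGUAGGUUGUGUGGUU"
  expect_equal(hairpin_df(enumerate_hairpins(s)), oracle_hairpins(s),
               ignore_attr = TRUE)
  set.seed(51)
  for (i in 1:300) {
    s <- random_rna(1, 8, 30)
    wob <- i %% 2 == 0
    got <- hairpin_df(enumerate_hairpins(s, allow_wobble = wob))
    exp <- oracle_hairpins(s, allow_wobble = wob)
    expect_equal(got, exp, ignore_attr = TRUE, label = s)
  }
})

test_that("every reported pair is chemically valid, nested and contiguous", {
  set.seed(52)
  for (s in random_rna(60, 10, 27)) {
    cc <- strsplit(s, "")[[1]]
    for (hp in enumerate_hairpins(s, min_stem = 1)) {
      p <- hp$pairs
      expect_true(all(p[, "i"] < p[, "j"]))
      expect_true(all(p >= 1 & p <= nchar(s)))
      valid <- c("AU", "UA", "GC", "CG", "GU", "UG")
      expect_true(all(paste0(cc[p[, "i"]], cc[p[, "j"]]) %in% valid))
      # nested and contiguous: k-th pair is (i0+k-1, j0-k+1)
      k <- seq_len(nrow(p)) - 1L
      expect_equal(p[, "i"], p[1, "i"] + k, ignore_attr = TRUE)
      expect_equal(p[, "j"], p[1, "j"] - k, ignore_attr = TRUE)
      # closing pair is innermost, adjacent to the loop
      expect_equal(p[nrow(p), "i"] + 1L, hp$loop_start, ignore_attr = TRUE)
      expect_equal(p[nrow(p), "j"] - 1L, hp$loop_end, ignore_attr = TRUE)
    }
  }
})

test_that("relaxing min_stem or widening the loop range never drops hairpins", {
  key <- function(hps) {
    vapply(hps, function(h) {
      sprintf("%d:%d:%d", h$stem_length, h$loop_start, h$loop_end)
    }, character(1))
  }
  set.seed(53)
  for (s in random_rna(40, 10, 27)) {
    strict <- key(enumerate_hairpins(s, min_stem = 3, loop_min = 4,
                                     loop_max = 6))
    relaxed <- key(enumerate_hairpins(s, min_stem = 2, loop_min = 3,
                                      loop_max = 8))
    expect_true(all(strict %in% relaxed))
  }
})

test_that("tetraloop cascade flags follow the filter definitions", {
  rec <- classify_tetraloop(enumerate_hairpins("GCCGAAAGGC")[[1]])
  expect_true(rec$loop_in_motif_set)
  expect_true(rec$stem_ge_3)
  expect_true(rec$closing_pair_cg)
  # UUCG loop with an A-U closing pair: motif yes, closing no
  hp2 <- enumerate_hairpins("CGAUUCGUCG")[[1]]
  expect_equal(hp2$loop_seq, "UUCG")
  expect_equal(hp2$closing_pair, c("A", "U"))
  rec2 <- classify_tetraloop(hp2)
  expect_true(rec2$loop_in_motif_set)
  expect_false(rec2$closing_pair_cg)
  # strict orientation distinguishes G(5')-C(3') from C(5')-G(3')
  hp3 <- enumerate_hairpins("GGGAAAACCC")[[1]]  # closing pair G-C
  expect_true(classify_tetraloop(hp3)$closing_pair_cg)
  expect_false(classify_tetraloop(hp3, closing_orientation = "strict")$closing_pair_cg)
})

test_that("planted tetraloop hairpins drive the cascade counts", {
  # 20 records with a planted GAAA tetraloop on a 3 bp stem; 8 closed C-G
  cg <- generate_library(synthetic_spec(8, planted_features = list(
    feature_hairpin(3, "GAAA", c("C", "G"), 1)), seed = 8))
  au <- generate_library(synthetic_spec(12, planted_features = list(
    feature_hairpin(3, "GAAA", c("A", "U"), 1)), seed = 9))
  lib <- mirna_library(
    c(paste0("cg-", cg$library$records$id),
      paste0("au-", au$library$records$id)),
    c(cg$library$records$sequence, au$library$records$sequence))
  casc <- tetraloop_cascade(lib, count = "all")
  gaaa <- casc[casc$motif == "GAAA", ]
  # every record carries a planted GAAA loop on a >= 3 bp stem
  expect_equal(gaaa$hairpin_formation, 20)
  expect_equal(gaaa$stem_ge_3, 20)
  # the 8 C-G-closed plantings pass the final stage; additional passes can
  # only come from chance non-planted loop placements
  expect_gte(gaaa$stem_ge_3_closing_cg, 8)
  # the planted closings themselves are exactly 8 C-G, by ground truth
  planted_cg <- sum(vapply(cg$truth$records, function(t) {
    sum(vapply(t$hairpins, function(h) {
      identical(h$closing_pair, c("C", "G"))
    }, logical(1)))
  }, numeric(1)))
  expect_equal(planted_cg, 8)
  expect_true(all(casc$hairpin_formation >= casc$stem_ge_3))
  expect_true(all(casc$stem_ge_3 >= casc$stem_ge_3_closing_cg))
})

test_that("cascade stages are monotone on arbitrary libraries", {
  set.seed(54)
  lib <- mirna_library(sprintf("r%02d", 1:40), random_rna(40, 14, 27))
  for (mode in c("best", "all")) {
    casc <- tetraloop_cascade(lib, count = mode)
    expect_true(all(casc$hairpin_formation >= casc$stem_ge_3))
    expect_true(all(casc$stem_ge_3 >= casc$stem_ge_3_closing_cg))
    tot <- casc[casc$motif == "Total", -1]
    expect_equal(unlist(tot),
                 colSums(casc[casc$motif != "Total", -1]),
                 ignore_attr = TRUE)
  }
})

test_that("stability score follows the stated arithmetic and is monotone in G:C", {
  hp <- enumerate_hairpins("GGGAAAACCC")[[1]]  # 3 G:C pairs, loop 4
  expect_equal(stability_score(hp), 3 * 3 - 0.5)
  hp_au <- enumerate_hairpins("CGAUUCGUCG")[[1]]  # A:U, G:C, C:G; loop 4
  expect_equal(stability_score(hp_au), 2 + 3 + 3 - 0.5)
  # adding one G:C pair at fixed loop strictly increases the score
  set.seed(55)
  for (k in 2:6) {
    stem_small <- strrep("G", k)
    stem_big <- strrep("G", k + 1)
    small <- enumerate_hairpins(paste0(stem_small, "AAAA",
                                       strrep("C", k)), min_stem = k)[[1]]
    big <- enumerate_hairpins(paste0(stem_big, "AAAA",
                                     strrep("C", k + 1)),
                              min_stem = k + 1)[[1]]
    expect_gt(stability_score(big), stability_score(small))
  }
})

test_that("dot-bracket output is balanced and positionally correct", {
  hp <- best_hairpin("GGGAAAACCC")
  expect_equal(dot_bracket(hp, 10), "(((....)))")
  s <- "UGAGGUAGUAGGUUGUGUGGUU"
  hp2 <- best_hairpin(s)
  db <- strsplit(dot_bracket(hp2, nchar(s)), "")[[1]]
  expect_equal(sum(db == "("), sum(db == ")"))
  expect_equal(which(db == "("), hp2$pairs[, "i"], ignore_attr = TRUE)
  expect_equal(sort(which(db == ")")), sort(hp2$pairs[, "j"]))
})
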