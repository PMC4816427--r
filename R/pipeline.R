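# End-to-end orchestration: ingest -> deduplicate -> composition -> motif
# and SSR censuses -> hairpin/tetraloop classification, producing a report
# bundle of tables plus a machine-readable manifest. All analysis stages
# are deterministic; randomness is confined to the synthetic generator.

#' Configuration for a characterization run
#'
#' Collects every analysis-relevant parameter with its default. Thresholds
#' are on the fraction scale where noted; coordinates throughout the
#' package are 1-based.
#'
#' @param input Path to a FASTA file, or a [synthetic_spec()].
#' @param species_prefix Optional id prefix filter (e.g. `"hsa-"`).
#' @param pp_threshold Purine/pyrimidine richness call threshold (strict
#'   `>`, default 0.70).
#' @param highly_rich_threshold Highly-rich flag threshold (default 0.90).
#' @param iim_motif Immunostimulatory motif to census (default `"UGUGU"`).
#' @param gu_min_tract Minimum alternating-GU tract length (default 5).
#' @param ssr_min_repeats Minimum complete repeats per SSR tract (default 3).
#' @param ssr_max_unit Maximum SSR unit length (default 5).
#' @param min_stem Minimum hairpin stem length in bp (default 3).
#' @param loop_min,loop_max Hairpin loop length bounds (defaults 3 and 8).
#' @param allow_wobble Permit G:U stem pairs (default `TRUE`).
#' @param tetraloop_set Loop motifs for the cascade (default
#'   [tetraloop_motifs()]).
#' @param closing_pair_orientation `"unordered"` or `"strict"`.
#' @param seed Seed forwarded to synthetic generation (ignored for file
#'   input).
#' @return A `run_config` object (a validated list).
#' @export
run_config <- function(input,
                       species_prefix = NULL,
                       pp_threshold = 0.70,
                       highly_rich_threshold = 0.90,
                       iim_motif = "UGUGU",
                       gu_min_tract = 5L,
                       ssr_min_repeats = 3L,
                       ssr_max_unit = 5L,
                       min_stem = 3L,
                       loop_min = 3L,
                       loop_max = 8L,
                       allow_wobble = TRUE,
                       tetraloop_set = tetraloop_motifs(),
                       closing_pair_orientation = c("unordered", "strict"),
                       seed = 1L) {
  closing_pair_orientation <- match.arg(closing_pair_orientation)
  stopifnot(pp_threshold > 0, pp_threshold < 1,
            highly_rich_threshold > 0, highly_rich_threshold <= 1,
            gu_min_tract >= 2L, ssr_min_repeats >= 2L,
            ssr_max_unit >= 1L, ssr_max_unit <= 5L,
            min_stem >= 1L, loop_min >= 3L, loop_min <= loop_max)
  validate_motif(normalize_sequence(iim_motif))
  structure(
    list(input = input,
         species_prefix = species_prefix,
         pp_threshold = pp_threshold,
         highly_rich_threshold = highly_rich_threshold,
         iim_motif = normalize_sequence(iim_motif),
         gu_min_tract = as.integer(gu_min_tract),
         ssr_min_repeats = as.integer(ssr_min_repeats),
         ssr_max_unit = as.integer(ssr_max_unit),
         min_stem = as.integer(min_stem),
         loop_min = as.integer(loop_min),
         loop_max = as.integer(loop_max),
         allow_wobble = isTRUE(allow_wobble),
         tetraloop_set = tetraloop_set,
         closing_pair_orientation = closing_pair_orientation,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# Stable hash of the analysis-relevant configuration (input identity is
# checksummed separately in the manifest).
config_hash <- function(config) {
  keys <- config[setdiff(names(config), "input")]
  keys$input_kind <- if (inherits(config$input, "synthetic_spec"))
    "synthetic" else "fasta"
  txt <- jsonlite::toJSON(keys, auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(txt), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full characterization pipeline
#'
#' Ingests the configured input (FASTA file or synthetic spec),
#' deduplicates, and computes every module's summary from the same
#' deduplicated library snapshot: length distribution, pooled base
#' content, positional frequency matrices (both anchors), terminal-base
#' table, purine/pyrimidine classification, motif census, GU-rich list,
#' SSR tract table and summary, hairpin loop-size census and tetraloop
#' cascade. Deterministic given input and config.
#'
#' @param config A [run_config()].
#' @param verbose Log record counts at stage boundaries (default `FALSE`).
#' @return An object of class `mirna_report` with components `library`
#'   (deduplicated), `n_input`, `length_distribution`, `composition`,
#'   `pfm_five_prime`, `pfm_three_prime`, `terminal_bases`,
#'   `pp_classification`, `iim_census`, `gu_rich`, `ssr`,
#'   `loop_census`, `tetraloop_cascade`, `truth` (synthetic input only),
#'   `config` and `manifest`.
#' @export
run_characterization <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  input_checksum <- NA_character_
  truth <- NULL
  if (inherits(config$input, "synthetic_spec")) {
    gen <- generate_library(config$input)
    lib <- gen$library
    truth <- gen$truth
  } else {
    lib <- read_mirna_fasta(config$input,
                            species_prefix = config$species_prefix)
    input_checksum <- unname(tools::md5sum(config$input))
  }
  n_input <- nrow(lib$records)
  say("ingest: %d records", n_input)
  lib <- deduplicate(lib)
  say("deduplicate: %d unique sequences", nrow(lib$records))
  if (nrow(lib$records) == 0L) {
    stop("no records remain after filtering/deduplication", call. = FALSE)
  }

  report <- list(
    library = lib,
    n_input = n_input,
    length_distribution = length_distribution(lib),
    composition = base_content(lib),
    pfm_five_prime = positional_frequency(lib, "five_prime"),
    pfm_three_prime = positional_frequency(lib, "three_prime"),
    terminal_bases = terminal_bases(lib),
    pp_classification = classify_pp(lib, threshold = config$pp_threshold,
                                    highly_rich_threshold =
                                      config$highly_rich_threshold),
    iim_census = find_iim(lib, motif = config$iim_motif),
    gu_rich = find_gu_rich(lib, min_length = config$gu_min_tract),
    ssr = ssr_summary(lib, min_repeats = config$ssr_min_repeats,
                      max_unit = config$ssr_max_unit),
    loop_census = loop_size_census(lib, min_stem = config$min_stem,
                                   loop_min = config$loop_min,
                                   loop_max = config$loop_max,
                                   allow_wobble = config$allow_wobble),
    tetraloop_cascade = tetraloop_cascade(
      lib, motif_set = config$tetraloop_set,
      allow_wobble = config$allow_wobble,
      closing_orientation = config$closing_pair_orientation),
    truth = truth,
    config = config
  )
  say("motifs: %d IIM-containing, %d GU-rich",
      nrow(report$iim_census), nrow(report$gu_rich))
  say("ssr: %d tracts", report$ssr$grand_total)
  report$manifest <- list(
    package = "mirchar",
    version = as.character(utils::packageVersion("mirchar")),
    config_hash = config_hash(config),
    input = if (inherits(config$input, "synthetic_spec"))
      sprintf("synthetic(n=%d, seed=%d)",
              config$input$n_sequences, config$input$seed)
      else config$input,
    input_checksum = input_checksum,
    n_input = n_input,
    n_unique = nrow(lib$records)
  )
  class(report) <- "mirna_report"
  report
}

#' @export
print.mirna_report <- function(x, ...) {
  cat("miRNA characterization report\n")
  cat(sprintf("  input:     %s\n", x$manifest$input))
  cat(sprintf("  records:   %d (%d unique)\n", x$n_input,
              nrow(x$library$records)))
  ld <- x$length_distribution
  mode_len <- names(ld$counts)[which.max(ld$counts)]
  cat(sprintf("  lengths:   %s-%s nt, mode %s (%d%%)\n",
              names(ld$counts)[1], names(ld$counts)[length(ld$counts)],
              mode_len, ld$percentages_rounded[mode_len]))
  comp <- round_half_up(100 * x$composition$fractions)
  cat(sprintf("  content:   A %d%%, C %d%%, G %d%%, U %d%%\n",
              comp["A"], comp["C"], comp["G"], comp["U"]))
  cat(sprintf("  P/P-rich:  %d purine, %d pyrimidine (> %d%%)\n",
              sum(x$pp_classification$call == "purine_rich"),
              sum(x$pp_classification$call == "pyrimidine_rich"),
              round_half_up(100 * x$config$pp_threshold)))
  cat(sprintf("  %s:     %d sequences; GU-rich: %d\n",
              x$config$iim_motif, nrow(x$iim_census), nrow(x$gu_rich)))
  cat(sprintf("  SSR:       %d tracts (%.2f per miRNA)\n",
              x$ssr$grand_total, round_half_up(x$ssr$grand_relative, 2)))
  cat(sprintf("  hairpins:  %d foldable sequences\n",
              attr(x$loop_census, "n_foldable")))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits every table of a [run_characterization()] report as TSV plus a
#' JSON manifest, laid out for side-by-side comparison with published
#' census tables (SSR summary with relative counts in parentheses,
#' three-column tetraloop cascade). Output is byte-deterministic for a
#' given input and configuration (no timestamps).
#'
#' @param report A `mirna_report`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "mirna_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  tsv(report$library$records[, c("id", "sequence", "length")], "library.tsv")
  ld <- report$length_distribution
  tsv(data.frame(length = names(ld$counts), count = ld$counts,
                 percent = ld$percentages_rounded),
      "length_distribution.tsv")
  comp <- report$composition
  tsv(data.frame(base = names(comp$counts), count = comp$counts,
                 fraction = comp$fractions),
      "composition.tsv")
  for (anchor in c("five_prime", "three_prime")) {
    m <- report[[paste0("pfm_", anchor)]]
    tsv(data.frame(position = seq_len(nrow(m)), unclass(m)[, RNA_BASES],
                   n_covering = attr(m, "n_covering")),
        sprintf("pfm_%s.tsv", anchor))
  }
  tsv(report$terminal_bases, "terminal_bases.tsv")
  tsv(report$pp_classification[, c("id", "sequence", "purine_pct",
                                   "pyrimidine_pct", "call", "highly_rich")],
      "pp_classification.tsv")
  tsv(report$iim_census, "iim_census.tsv")
  tsv(report$gu_rich, "gu_rich.tsv")
  tsv(report$ssr$tracts, "ssr_tracts.tsv")
  labels <- c("mono", "di", "tri", "tetra", "penta")
  s <- report$ssr
  tsv(data.frame(
    unit_length = labels[seq_along(s$totals)],
    total = sprintf("%d (%.2f)", s$totals,
                    round_half_up(s$relative_counts, 2))),
      "ssr_summary.tsv")
  tsv(report$loop_census, "loop_census.tsv")
  tsv(report$tetraloop_cascade, "tetraloop_cascade.tsv")
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths[[length(paths) + 1L]] <- manifest_path
  invisible(unlist(paths))
}
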