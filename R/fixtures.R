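# Reference fixtures: the published purine/pyrimidine-rich, GU-rich and
# UGUGU-containing miRNA tables, stored verbatim (ids and sequences as
# printed, including typographical quirks) so censuses can be regression-
# tested without any download.

#' Published highly purine/pyrimidine-rich miRNAs
#'
#' The 11 printed sequences (5 pyrimidine-rich, 6 purine-rich, all with the
#' dominant class at 90% or more). `printed_pct` and `printed_length` are
#' the published values. Note: hsa-miR-4271 is printed with a 19-nt
#' sequence but a stated length of 22; the discrepancy is preserved and
#' flagged via `length_discrepancy`, never silently fixed.
#'
#' @return A data.frame with columns `id`, `sequence`, `printed_pct`,
#'   `printed_length`, `group` and `length_discrepancy`.
#' @export
pp_rich_mirnas <- function() {
  df <- data.frame(
    id = c("hsa-miR-4290", "hsa-miR-1281", "hsa-miR-4716-5p",
           "hsa-miR-483-3p", "hsa-miR-877-3p",
           "hsa-miR-6124", "hsa-miR-4271", "hsa-miR-483-5p",
           "hsa-miR-4644", "hsa-miR-4716-3p", "hsa-miR-1234-5p"),
    sequence = c(
      "UGCCCUCCUUUCUUCCCUC",
      "UCGCCUCCUCCUCUCCC",
      "UCCAUGUUUCCUUCCCCCUUCU",
      "UCACUCCUCUCCUCCCGUCUU",
      "UCCUCUUCUCCCUCCUCCCAG",
      "GGGAAAAGGAAGGGGGAGGA",
      "GGGGGAAGAAAAGGUGGGG",
      "AAGACGGGAGGAAAGAAGGGAG",
      "UGGAGAGAGAAAAGAGACAGAAG",
      "AAGGGGGAAGGAAACAUGGAGA",
      "GGGGGGGGGGGGGGGGGGCCG"
    ),
    printed_pct = c(95, 94, 91, 90, 90, 100, 95, 95, 91, 91, 90),
    printed_length = c(19, 17, 22, 21, 21, 20, 22, 22, 23, 22, 21),
    group = c(rep("pyrimidine_rich", 5), rep("purine_rich", 6)),
    stringsAsFactors = FALSE
  )
  df$length_discrepancy <- nchar(df$sequence) != df$printed_length
  df
}

#' Published GU-rich miRNAs
#'
#' The 23 printed GU-rich sequences (every one carries a maximal
#' alternating-GU tract of at least 5 nt).
#'
#' @return A data.frame with columns `id`, `sequence`.
#' @export
gu_rich_mirnas <- function() {
  data.frame(
    id = c("miR-574-5p", "miR-941", "miR-3149", "miR-1238-5p",
           "miR-545-3p", "miR-2278", "miR-3148", "let-7b-5p",
           "miR-493-3p", "miR-1180", "miR-539-5p", "miR-32-3p",
           "miR-206", "miR-1299", "miR-3911", "miR-297", "miR-610",
           "miR-1228-5p", "miR-595", "miR-4455", "miR-3650",
           "miR-147a", "miR-660-3p"),
    sequence = c(
      "UGAGUGUGUGUGUGUGAGUGUGU",
      "CACCCGGCUGUGUGCACAUGUGC",
      "UUUGUAUGGAUAUGUGUGUGUAU",
      "GUGAGUGGGAGCCCCAGUGUGUG",
      "UCAGCAAACAUUUAUUGUGUGC",
      "GAGAGCAGUGUGUGUUGCCUGG",
      "UGGAAAAAACUGGUGUGUGCUU",
      "UGAGGUAGUAGGUUGUGUGGUU",
      "UGAAGGUCUACUGUGUGCCAGG",
      "UUUCCGGCUCGCGUGGGUGUGU",
      "GGAGAAAUUAUCCUUGGUGUGU",
      "CAAUUUAGUGUGUGUGAUAUUU",
      "UGGAAUGUAAGGAAGUGUGUGG",
      "UUCUGGAAUUCUGUGUGAGGGA",
      "UGUGUGGAUCCUGGAGGAGGCA",
      "AUGUAUGUGUGCAUGUGCAUG",
      "UGAGCUAAAUGUGUGCUGGGA",
      "GUGGGCGGGGGCAGGUGUGUG",
      "GAAGUGUGCCGUGGUGUGUCU",
      "AGGGUGUGUGUGUUUUU",
      "AGGUGUGUCUGUAGAGUCC",
      "GUGUGUGGAAAUGCUUCUGC",
      "ACCUCCUGUGUGCAUGGAUUA"
    ),
    stringsAsFactors = FALSE
  )
}

#' Published UGUGU-containing (interferon-induction-motif) miRNAs
#'
#' The 50 printed sequences with at least one 5'-UGUGU-3' occurrence. Ids
#' are stored exactly as printed (including the "iR-642a-5p" typo for
#' miR-642a-5p, and a spelling of miR-3149 one U shorter than in the
#' GU-rich table).
#'
#' @return A data.frame with columns `id`, `sequence`.
#' @export
iim_mirnas <- function() {
  data.frame(
    id = c(
      "miR-3682-5p", "miR-2278", "miR-1238-5p", "miR-3149", "let-7b-5p",
      "miR-4455", "miR-4717-5p", "miR-573", "miR-660-3p", "miR-378a-5p",
      "miR-599", "miR-1226-3p", "miR-1270", "miR-610", "miR-3911",
      "miR-3650", "miR-4789-5p", "miR-330-5p", "miR-941", "miR-597",
      "miR-5580-5p", "miR-4700-5p", "miR-892a", "miR-206", "miR-595",
      "miR-539-5p", "miR-1180-3p", "miR-450a-5p", "miR-493-3p", "miR-4669",
      "miR-4753-3p", "miR-624-5p", "miR-3657", "miR-3148", "miR-3177-5p",
      "miR-581", "miR-642b-5p", "miR-147a", "miR-592", "miR-545-3p",
      "miR-1228-5p", "iR-642a-5p", "miR-3152-3p", "miR-32-3p", "miR-1299",
      "miR-297", "miR-187-3p", "miR-5010-3p", "miR-574-5p", "miR-649"
    ),
    sequence = c(
      "CUACUUCUACCUGUGUUAUCAU",
      "GAGAGCAGUGUGUGUUGCCUGG",
      "GUGAGUGGGAGCCCCAGUGUGUG",
      "UUGUAUGGAUAUGUGUGUGUAU",
      "UGAGGUAGUAGGUUGUGUGGUU",
      "AGGGUGUGUGUGUUUUU",
      "UAGGCCACAGCCACCCAUGUGU",
      "CUGAAGUGAUGUGUAACUGAUCAG",
      "ACCUCCUGUGUGCAUGGAUUA",
      "CUCCUGACUCCAGGUCCUGUGU",
      "GUUGUGUCAGUUUAUCAAAC",
      "UCACCAGCCCUGUGUUCCCUAG",
      "CUGGAGAUAUGGAAGAGCUGUGU",
      "UGAGCUAAAUGUGUGCUGGGA",
      "UGUGUGGAUCCUGGAGGAGGCA",
      "AGGUGUGUCUGUAGAGUCC",
      "GUAUACACCUGAUAUGUGUAUG",
      "UCUCUGGGCCUGUGUCUUAGGC",
      "CACCCGGCUGUGUGCACAUGUGC",
      "UGUGUCACUCGAUGACCACUGU",
      "UGCUGGCUCAUUUCAUAUGUGU",
      "UCUGGGGAUGAGGACAGUGUGU",
      "CACUGUGUCCUUUCUGCGUAG",
      "UGGAAUGUAAGGAAGUGUGUGG",
      "GAAGUGUGCCGUGGUGUGUC",
      "GGAGAAAUUAUCCUUGGUGUGU",
      "UUUCCGGCUCGCGUGGGUGUGU",
      "UUUUGCGAUGUGUUCCUAAUAU",
      "UGAAGGUCUACUGUGUGCCAGG",
      "UGUGUCCGGGAAGUGGAGGAGG",
      "UUCUCUUUCUUUAGCCUUGUGU",
      "UAGUACCAGUACCUUGUGUUCA",
      "UGUGUCCCAUUAUUGGUGAUU",
      "UGGAAAAAACUGGUGUGUGCUU",
      "UGUGUACACACGUGCCAGGCGCU",
      "UCUUGUGUUCUCUAGAUCAGU",
      "GGUUCCCUCUCCAAAUGUGUCU",
      "GUGUGUGGAAAUGCUUCUGC",
      "UUGUGUCAAUAUGCGAUGAUGU",
      "UCAGCAAACAUUUAUUGUGUGC",
      "GUGGGCGGGGGCAGGUGUGUG",
      "GUCCCUCUCCAAAUGUGUCUUG",
      "UGUGUUAGAAUAGGGGCAAUAA",
      "CAAUUUAGUGUGUGUGAUAUUU",
      "UUCUGGAAUUCUGUGUGAGGGA",
      "AUGUAUGUGUGCAUGUGCAUG",
      "UCGUGUCUUGUGUUGCAGCCGG",
      "UUUUGUGUCUCCCAUUCCCCAG",
      "UGAGUGUGUGUGUGUGAGUGUGU",
      "AAACCUGUGUUGUUCAAGAGUC"
    ),
    stringsAsFactors = FALSE
  )
}

#' Write the reference tables as FASTA fixtures
#'
#' Emits three FASTA files (`pp_rich.fa`, `gu_rich.fa`,
#' `iim.fa`) whose records are exactly the printed sequences with
#' the printed names as ids.
#'
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture_fasta <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    pp_rich = pp_rich_mirnas(),
    gu_rich = gu_rich_mirnas(),
    iim = iim_mirnas()
  )
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    path <- file.path(dir, paste0(nm, ".fa"))
    write_mirna_fasta(mirna_library(tb$id, tb$sequence, source = nm), path)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Load one of the reference tables as a library
#'
#' @param table One of `"pp_rich"`, `"gu_rich"`, `"iim"`.
#' @return A [mirna_library()] built from the printed rows.
#' @export
fixture_library <- function(table = c("pp_rich", "gu_rich", "iim")) {
  table <- match.arg(table)
  tb <- switch(table,
               pp_rich = pp_rich_mirnas(),
               gu_rich = gu_rich_mirnas(),
               iim = iim_mirnas())
  mirna_library(tb$id, tb$sequence, source = table)
}
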