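# Internal helpers shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

#' Round half away from zero
#'
#' Rounding convention used for all printed percentages and relative counts:
#' ties go away from zero (so 90.5 -> 91), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), digits = 0)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Split sequences into character vectors (list, one element per sequence).
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Uppercase and map DNA-style T/t to U/u before validation.
normalize_sequence <- function(x) toupper(chartr("Tt", "Uu", x))

# Abort (naming the first offending id) if any sequence contains a character
# outside A/C/G/U after normalization. Silent drops would corrupt downstream
# census counts, so validation failures are fatal.
validate_sequences <- function(sequences, ids = NULL) {
  bad <- grepl("[^ACGU]", sequences)
  if (any(bad)) {
    i <- which(bad)[1L]
    label <- if (is.null(ids)) sprintf("record %d", i) else ids[i]
    offending <- regmatches(sequences[i], regexpr("[^ACGU]", sequences[i]))
    stop(sprintf(
      "invalid character '%s' in sequence of '%s' (alphabet is A, C, G, U after T->U mapping)",
      offending, label
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# Check a motif/unit string over the RNA alphabet.
validate_motif <- function(motif, what = "motif") {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop(sprintf("%s must be a single non-empty string", what), call. = FALSE)
  }
  if (grepl("[^ACGU]", motif)) {
    stop(sprintf("%s '%s' contains characters outside {A,C,G,U}", what, motif),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards (so library generation never perturbs user randomness).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
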