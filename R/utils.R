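# Internal sequence utilities shared across modules.

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and converts T to U. DNA and RNA inputs are unified to one
#' alphabet so ESTs (DNA) and mature miRNAs (RNA) can be compared directly.
#' IUPAC ambiguity codes are tolerated; gap characters are not.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector over {A,C,G,U} plus IUPAC ambiguity codes.
#' @export
#' @examples
#' normalize_rna("acgt")
normalize_rna <- function(seq) {
  out <- chartr("T", "U", toupper(seq))
  bad <- !grepl(paste0("^[", paste(c(RNA_BASES, IUPAC_EXTRA), collapse = ""), "]*$"), out)
  if (any(bad)) {
    abort(paste0(
      "invalid characters in sequence(s): ",
      paste(utils::head(which(bad), 3L), collapse = ", "),
      " (gaps and non-IUPAC letters are not allowed)"
    ))
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A<->U, G<->C), reversed. Ambiguity codes are an
#' error: mismatch counting and pairing over them is ill-defined, so they are
#' rejected wherever a sequence enters scoring.
#'
#' @param seq Character vector of RNA sequences over {A,C,G,U}.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AUGC") # "GCAU"
reverse_complement <- function(seq) {
  assert_unambiguous(seq)
  comp <- chartr("ACGU", "UGCA", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

assert_unambiguous <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    abort(paste0(what, " contains ambiguity codes or invalid letters; ",
                 "only A/C/G/U are allowed in scoring contexts"))
  }
  invisible(seq)
}

# Split into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Deterministic RNG scope: all generators take a mandatory seed and never
# touch the global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  withr::with_seed(as.integer(seed), code)
}

random_rna <- function(n, gc_bias = 0.5, weights = NULL) {
  if (is.null(weights)) {
    weights <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
                 G = gc_bias / 2, U = (1 - gc_bias) / 2)
  }
  paste(sample(names(weights), n, replace = TRUE, prob = weights), collapse = "")
}
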