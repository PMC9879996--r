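# DNA alphabet helpers shared by the scanner, classifier and simulator.

#' IUPAC nucleotide code expansions
#'
#' Named list mapping each IUPAC nucleotide letter to the set of
#' unambiguous bases it stands for (`N` expands to all four).
#'
#' @format Named list of character vectors.
#' @export
iupac_codes <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")

#' Complement and reverse-complement of DNA strings
#'
#' Vectorised over character vectors; IUPAC ambiguity letters are
#' complemented to their ambiguity-complement (e.g. `R` to `Y`).
#'
#' @param x Character vector of DNA strings (or single letters).
#' @return Character vector of the same length.
#' @examples
#' dna_complement("TTTA")
#' dna_revcomp("TTTA")
#' @export
dna_complement <- function(x) {
  chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
         "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
}

#' @rdname dna_complement
#' @export
dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split a DNA string into an uppercase character vector, validating the
# alphabet against the IUPAC letters.
seq_chars <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(iupac_codes))
  if (length(bad) > 0) {
    abort(paste0(what, " contains non-IUPAC characters: ",
                 paste(bad, collapse = ", ")),
          class = "mbescope_input_error")
  }
  chars
}

# Replace one base in a sequence string (1-based).
set_base <- function(seq, at, base) {
  substr(seq, at, at) <- base
  seq
}
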