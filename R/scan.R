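# Oriented PAM placement enumeration and protospacer coordinate
# arithmetic.
#
# All coordinates in the placement tibbles are 1-based inclusive on the
# plus strand of the scanned sequence (VCF-compatible).  Protospacer
# positions follow the editor's convention: under cas12f_r_zero the R
# of the PAM is position 0 and the base immediately 3' of it is
# position 1; under spcas9_pam_distal positions run 1..L from the
# PAM-distal protospacer end.

# Match offsets (1-based starts) of an IUPAC pattern in a character
# vector.  Matching rule: an unambiguous sequence base matches any
# pattern letter whose IUPAC expansion contains it; an ambiguous
# sequence letter (N, R, ...) matches only the identical pattern
# letter.  Overlapping matches are all reported.
iupac_match_starts <- function(chars, pat_chars) {
  n <- length(chars)
  m <- length(pat_chars)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    allowed <- unique(c(intersect(iupac_codes[[pat_chars[j]]], DNA_BASES),
                        pat_chars[j]))
    ok <- ok & chars[j:(n - m + j)] %in% allowed
  }
  which(ok)
}

#' Enumerate oriented PAM placements on a sequence
#'
#' Scans both strands of `seq` for matches to the editor's PAM pattern
#' and returns every placement whose full protospacer lies within the
#' sequence. Overlapping matches are all reported; deduplication, if
#' wanted, is the caller's job. An `N` in the sequence matches only an
#' `N` in the pattern (conservative scanning for design use).
#'
#' @param seq DNA string over the IUPAC alphabet.
#' @param spec A [base_editor_spec()].
#' @param contig Contig name recorded in the output.
#' @param protospacer_length Protospacer length; defaults to the
#'   spec's (20 nt).
#' @return A tibble with one row per placement: `contig`, `strand`
#'   (`"+"`/`"-"`), `pam_start`, `pam_end`, `anchor` (genomic index of
#'   the convention anchor: the R base for `cas12f_r_zero`, the
#'   PAM-proximal protospacer end for `spcas9_pam_distal`),
#'   `proto_start`, `proto_end`, `editor`, `convention`. All
#'   coordinates 1-based inclusive on the plus strand, sorted by
#'   (`pam_start`, `strand`).
#' @examples
#' spec <- load_registry()[["miniABE-any"]]
#' find_pam_sites(paste0("GTTTA", strrep("G", 21)), spec)
#' @export
find_pam_sites <- function(seq, spec, contig = "seq",
                           protospacer_length = spec$protospacer_length) {
  stopifnot(inherits(spec, "base_editor_spec"))
  chars <- seq_chars(seq)
  n <- length(chars)
  pat <- strsplit(spec$pam, "", fixed = TRUE)[[1]]
  m <- length(pat)
  L <- as.integer(protospacer_length)

  plus_starts <- iupac_match_starts(chars, pat)
  rc_chars <- rev(strsplit(dna_complement(paste(chars, collapse = "")),
                           "", fixed = TRUE)[[1]])
  rc_starts <- iupac_match_starts(rc_chars, pat)
  # footprint of a revcomp match starting at s' covers plus coords
  # [n - s' - m + 2, n - s' + 1]
  minus_fp_start <- n - rc_starts - m + 2L

  geom <- function(fp_start, strand) {
    fp_end <- fp_start + m - 1L
    if (spec$convention == "cas12f_r_zero") {
      if (strand == "+") {
        anchor <- fp_end
        proto_start <- anchor + 1L; proto_end <- anchor + L
      } else {
        anchor <- fp_start
        proto_start <- anchor - L; proto_end <- anchor - 1L
      }
    } else { # spcas9_pam_distal, PAM 3' of protospacer
      if (strand == "+") {
        proto_start <- fp_start - L; proto_end <- fp_start - 1L
        anchor <- proto_end
      } else {
        proto_start <- fp_end + 1L; proto_end <- fp_end + L
        anchor <- proto_start
      }
    }
    keep <- proto_start >= 1L & proto_end <= n
    tibble(contig = contig, strand = strand,
           pam_start = fp_start[keep], pam_end = fp_end[keep],
           anchor = anchor[keep],
           proto_start = proto_start[keep], proto_end = proto_end[keep])
  }

  out <- bind_rows(geom(plus_starts, "+"), geom(minus_fp_start, "-"))
  out$editor <- spec$name
  out$convention <- spec$convention
  out <- arrange(out, .data$pam_start, .data$strand)
  class(out) <- c("pam_placements", class(out))
  out
}

#' Convert genomic indices to protospacer positions
#'
#' Vectorised over the rows of `placements` (with `genomic_index`
#' recycled, or vice versa). Under `cas12f_r_zero` the anchor (the R of
#' the PAM) maps to position 0 and positions run 0..L; on the minus
#' strand the arithmetic is mirrored. Under `spcas9_pam_distal` valid
#' positions run 1..L. Indices outside the valid range map to `NA`.
#'
#' @param placements A placements tibble from [find_pam_sites()].
#' @param genomic_index Integer vector of 1-based plus-strand indices.
#' @param convention If supplied, checked against the placements'
#'   convention; a mismatch is a usage error.
#' @return Integer vector of protospacer positions (`NA` outside the
#'   protospacer/anchor range).
#' @export
protospacer_position <- function(placements, genomic_index,
                                 convention = NULL) {
  if (!is.null(convention) &&
      !all(placements$convention == convention)) {
    abort("convention does not match these placements",
          class = "mbescope_usage_error")
  }
  g <- as.integer(genomic_index)
  k <- max(nrow(placements), length(g))
  g <- rep_len(g, k)
  col <- function(x) rep_len(x, k)
  strand <- col(placements$strand)
  conv <- col(placements$convention)
  anchor <- col(placements$anchor)
  proto_start <- col(placements$proto_start)
  proto_end <- col(placements$proto_end)
  L <- proto_end - proto_start + 1L
  pos <- ifelse(conv == "cas12f_r_zero",
                ifelse(strand == "+", g - anchor, anchor - g),
                ifelse(strand == "+", g - proto_start + 1L,
                       proto_end - g + 1L))
  lo <- ifelse(conv == "cas12f_r_zero", 0L, 1L)
  pos <- as.integer(pos)
  pos[pos < lo | pos > L] <- NA_integer_
  pos
}

#' Convert protospacer positions to genomic indices
#'
#' Inverse of [protospacer_position()]; vectorised the same way.
#'
#' @inheritParams protospacer_position
#' @param position Integer vector of protospacer positions.
#' @return Integer vector of 1-based plus-strand genomic indices (`NA`
#'   for positions outside the valid range).
#' @export
genomic_index_at <- function(placements, position, convention = NULL) {
  if (!is.null(convention) &&
      !all(placements$convention == convention)) {
    abort("convention does not match these placements",
          class = "mbescope_usage_error")
  }
  p <- as.integer(position)
  k <- max(nrow(placements), length(p))
  p <- rep_len(p, k)
  col <- function(x) rep_len(x, k)
  strand <- col(placements$strand)
  conv <- col(placements$convention)
  anchor <- col(placements$anchor)
  proto_start <- col(placements$proto_start)
  proto_end <- col(placements$proto_end)
  L <- proto_end - proto_start + 1L
  lo <- ifelse(conv == "cas12f_r_zero", 0L, 1L)
  g <- ifelse(conv == "cas12f_r_zero",
              ifelse(strand == "+", anchor + p, anchor - p),
              ifelse(strand == "+", proto_start + p - 1L,
                     proto_end - p + 1L))
  g <- as.integer(g)
  g[p < lo | p > L] <- NA_integer_
  g
}

# Base seen by the editor (i.e. on the placement strand) at a genomic
# index, given the plus-strand character vector of the sequence.
strand_base <- function(chars, g, strand) {
  b <- chars[g]
  strand <- rep_len(strand, length(b))
  out <- b
  out[strand == "-"] <- dna_complement(b[strand == "-"])
  out
}

#' Write placements to TSV
#'
#' @param placements Tibble from [find_pam_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements_tsv <- function(placements, path) {
  readr::write_tsv(as_tibble(placements), path)
  invisible(path)
}
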