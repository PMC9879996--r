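# In-code fixtures shared across test files.

toy_abe <- function(window = 3:4, precision = window, ...) {
  base_editor_spec("toyABE", "A", "G", "TTTR", "five_prime",
                   "cas12f_r_zero", activity_window = window,
                   precision_window = precision, ...)
}

toy_cbe <- function(window = 3L, precision = window, ...) {
  base_editor_spec("toyCBE", "C", "T", "TTTR", "five_prime",
                   "cas12f_r_zero", activity_window = window,
                   precision_window = precision, ...)
}

toy_spcas9_cbe <- function(window = 4:8, ...) {
  base_editor_spec("toy49", "C", "T", "NGG", "three_prime",
                   "spcas9_pam_distal", activity_window = window, ...)
}

# A random variant with a 30-nt flank radius.  Half the draws plant a
# PAM at an offset that may or may not put the centre in the window,
# and bias ref/alt towards chemistry-compatible classes, so positive
# verdicts are well represented; the rest are uniform background.
random_variant <- function(spec, radius = 30L) {
  width <- 2L * radius + 1L
  center <- radius + 1L
  chars <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  if (runif(1) < 0.5) {
    m <- nchar(spec$pam)
    t <- sample(1:20, 1) # target position, possibly outside the window
    if (spec$convention == "cas12f_r_zero") {
      pam_start <- center - t - m + 1L
    } else {
      pam_start <- center - t + 1L + spec$protospacer_length
    }
    pam <- vapply(strsplit(spec$pam, "", fixed = TRUE)[[1]], function(p) {
      opts <- intersect(mbescope::iupac_codes[[p]], c("A", "C", "G", "T"))
      opts[sample.int(length(opts), 1)]
    }, character(1))
    chars[pam_start:(pam_start + m - 1L)] <- pam
    if (runif(1) < 0.8) {
      ref <- spec$edit_to; alt <- spec$edit_from
    } else {
      pair <- sample(c("A", "C", "G", "T"), 2)
      ref <- pair[1]; alt <- pair[2]
    }
    if (runif(1) < 0.5) {
      chars <- rev(strsplit(dna_complement(paste(chars, collapse = "")),
                            "", fixed = TRUE)[[1]])
      ref <- dna_complement(ref); alt <- dna_complement(alt)
    }
  } else {
    pair <- sample(c("A", "C", "G", "T"), 2)
    ref <- pair[1]; alt <- pair[2]
  }
  chars[center] <- ref
  list(flank = paste(chars, collapse = ""), ref = ref, alt = alt)
}

# Amplicon of the given radius around a planted plus-strand placement
# whose protospacer holds the substrate base at `substrate_at`.
planted_amplicon <- function(spec, substrate_at, radius = 40L) {
  width <- 2L * radius + 1L
  center <- radius + 1L
  chars <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  m <- nchar(spec$pam)
  t0 <- substrate_at[1]
  if (spec$convention == "cas12f_r_zero") {
    anchor <- center - t0
    pam_start <- anchor - m + 1L
  } else {
    pam_start <- center - t0 + 1L + spec$protospacer_length
  }
  pam <- vapply(strsplit(spec$pam, "", fixed = TRUE)[[1]], function(p) {
    opts <- intersect(mbescope::iupac_codes[[p]], c("A", "C", "G", "T"))
    opts[sample.int(length(opts), 1)]
  }, character(1))
  chars[pam_start:(pam_start + m - 1L)] <- pam
  not_sub <- setdiff(c("A", "C", "G", "T"), spec$edit_from)
  for (q in 1:spec$protospacer_length) {
    g <- center - t0 + q
    chars[g] <- if (q %in% substrate_at) spec$edit_from else {
      sample(not_sub, 1)
    }
  }
  paste(chars, collapse = "")
}

# Locate the planted placement (anchor = center - t0 geometry) among
# the scanner's results so tests do not depend on incidental PAMs.
planted_design <- function(ref_seq, spec, substrate_at, radius = 40L) {
  center <- radius + 1L
  t0 <- substrate_at[1]
  pl <- find_pam_sites(ref_seq, spec)
  pos <- protospacer_position(pl, center)
  row <- which(pl$strand == "+" & !is.na(pos) & pos == t0)[1]
  amplicon_design(ref_seq, spec, placement = pl[row, , drop = FALSE])
}
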