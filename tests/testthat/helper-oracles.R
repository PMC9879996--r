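# Independent brute-force oracles used to validate the scanner and
# the targetability classifier.  They deliberately share no code with
# the implementation: PAM matching goes through a PCRE lookahead regex
# (or a per-offset character loop), and placement geometry is worked
# out in each strand's own coordinate frame.

iupac_class <- function(letter) {
  e <- unique(c(intersect(mbescope::iupac_codes[[letter]],
                          c("A", "C", "G", "T")), letter))
  if (length(e) == 1) e else paste0("[", paste(e, collapse = ""), "]")
}

iupac_regex <- function(pam) {
  paste(vapply(strsplit(pam, "", fixed = TRUE)[[1]], iupac_class,
               character(1)),
        collapse = "")
}

# All 1-based start offsets (overlapping) of an IUPAC pattern in a
# string, via PCRE lookahead.
oracle_match_starts <- function(s, pam) {
  hits <- gregexpr(paste0("(?=", iupac_regex(pam), ")"), s,
                   perl = TRUE)[[1]]
  as.integer(hits[hits > 0])
}

# Oracle placement set: (strand, plus-strand PAM start) pairs for
# placements whose protospacer fits inside the sequence.
oracle_pam_sites <- function(seq, spec, L = 20L) {
  n <- nchar(seq)
  m <- nchar(spec$pam)
  plus <- oracle_match_starts(seq, spec$pam)
  minus_rc <- oracle_match_starts(dna_revcomp(seq), spec$pam)
  minus <- n - minus_rc - m + 2L # plus-strand footprint start
  if (spec$convention == "cas12f_r_zero") {
    plus <- plus[plus + m - 1L + L <= n]
    minus <- minus[minus - L >= 1L]
  } else {
    plus <- plus[plus - L >= 1L]
    minus <- minus[minus + m - 1L + L <= n]
  }
  out <- rbind(
    data.frame(strand = rep("+", length(plus)), pam_start = plus),
    data.frame(strand = rep("-", length(minus)), pam_start = minus)
  )
  out[order(out$pam_start, out$strand), , drop = FALSE]
}

# Per-offset PAM test used inside the classifier oracle (loop, not
# regex, so the two oracles are themselves written differently).
pam_matches_at <- function(chars, off, pam_expansions) {
  for (j in seq_along(pam_expansions)) {
    if (!(chars[off + j - 1L] %in% pam_expansions[[j]])) return(FALSE)
  }
  TRUE
}

# Brute-force targetability oracle: mutate the flank to the alt
# allele, enumerate every offset on both strands, and simulate the
# edit.  Returns list(correctable, precise).
oracle_classify <- function(flank, ref, alt, spec) {
  L <- spec$protospacer_length
  m <- nchar(spec$pam)
  width <- nchar(flank)
  center <- (width + 1L) %/% 2L
  substr(flank, center, center) <- alt
  pam_exp <- lapply(strsplit(spec$pam, "", fixed = TRUE)[[1]],
                    function(p) unique(c(intersect(
                      mbescope::iupac_codes[[p]], c("A", "C", "G", "T")),
                      p)))
  correctable <- FALSE
  precise <- FALSE
  for (strand in c("+", "-")) {
    s <- if (strand == "+") flank else dna_revcomp(flank)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    center_s <- if (strand == "+") center else width - center + 1L
    # edit on this strand must restore the plus-strand ref allele
    restores <- if (strand == "+") spec$edit_to == ref else {
      dna_complement(spec$edit_to) == ref
    }
    if (!restores) next
    for (off in seq_len(width - m + 1L)) {
      if (!pam_matches_at(chars, off, pam_exp)) next
      pos_index <- function(q) {
        if (spec$convention == "cas12f_r_zero") off + m - 1L + q else {
          off - L + q - 1L
        }
      }
      if (pos_index(1L) < 1L || pos_index(L) > width ||
            pos_index(L) < 1L || pos_index(1L) > width) {
        next
      }
      hit_q <- NULL
      for (q in spec$activity_window) {
        if (pos_index(q) == center_s &&
              chars[pos_index(q)] == spec$edit_from) {
          hit_q <- q
        }
      }
      if (is.null(hit_q)) next
      correctable <- TRUE
      bystanders <- 0L
      for (q in setdiff(spec$activity_window, hit_q)) {
        if (chars[pos_index(q)] == spec$edit_from) {
          bystanders <- bystanders + 1L
        }
      }
      if (hit_q %in% spec$precision_window && bystanders == 0L) {
        precise <- TRUE
      }
    }
  }
  list(correctable = correctable, precise = precise)
}
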