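# Quantification of base-editing outcomes from amplicon reads.
#
# The read model is gapless: reads are full-length copies of the
# amplicon reference (indel-containing reads are rejected by length;
# indel calling is out of scope).  All editing statistics derive from
# one object, the per-position substitution matrix.

#' Define an amplicon design
#'
#' Binds an amplicon reference sequence to the PAM placement locating
#' the protospacer within it and the editor used. If `placement` is
#' omitted the first placement found on the reference is used (an
#' error if there is none); any supplied placement is re-validated
#' against the reference.
#'
#' @param reference Amplicon reference sequence (DNA string).
#' @param spec A [base_editor_spec()].
#' @param placement Optional one-row tibble from [find_pam_sites()].
#' @param contig Contig/amplicon name.
#' @return An object of class `amplicon_design`.
#' @export
amplicon_design <- function(reference, spec, placement = NULL,
                            contig = "amplicon") {
  reference <- paste(seq_chars(reference), collapse = "")
  found <- find_pam_sites(reference, spec, contig = contig)
  if (is.null(placement)) {
    if (nrow(found) == 0) {
      abort("no PAM placement of this editor on the reference",
            class = "mbescope_usage_error")
    }
    placement <- found[1, , drop = FALSE]
  } else {
    placement <- as_tibble(placement)[1, , drop = FALSE]
    key <- c("strand", "pam_start", "pam_end", "proto_start", "proto_end")
    hit <- vapply(seq_len(nrow(found)), function(i) {
      all(unlist(found[i, key]) == unlist(placement[key]))
    }, logical(1))
    if (!any(hit)) {
      abort("placement does not re-validate against the reference sequence",
            class = "mbescope_validation_error")
    }
  }
  structure(list(reference = reference, placement = placement,
                 spec = spec, contig = contig),
            class = "amplicon_design")
}

#' @exportS3Method base::print
print.amplicon_design <- function(x, ...) {
  cat(sprintf("<amplicon_design> %s: %d nt, editor %s, protospacer %d-%d (%s)\n",
              x$contig, nchar(x$reference), x$spec$name,
              x$placement$proto_start, x$placement$proto_end,
              x$placement$strand))
  invisible(x)
}

#' Tally per-position base calls from amplicon reads
#'
#' Counts, at every reference position, the number of reads calling
#' each of A/C/G/T. Calls of `N` (or any non-ACGT letter) are excluded
#' from the informative depth at that position. Reads whose length
#' differs from the reference are rejected (gapless model); the
#' rejected count is recorded, and more than 50% rejections is a hard
#' error.
#'
#' @param reads Character vector of reads, same orientation as the
#'   reference.
#' @param design An [amplicon_design()].
#' @return A `substitution_matrix`: a tibble with columns `pos`, `ref`,
#'   `A`, `C`, `G`, `T`, `depth`, carrying the design and read counts
#'   as attributes.
#' @export
tabulate_substitutions <- function(reads, design) {
  stopifnot(inherits(design, "amplicon_design"))
  len <- nchar(design$reference)
  ok <- nchar(reads) == len
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warn(sprintf("%d/%d reads rejected (length != %d)",
                 n_rejected, length(reads), len))
    if (n_rejected > length(reads) / 2) {
      abort("more than 50% of reads rejected by length",
            class = "mbescope_input_error")
    }
  }
  reads <- toupper(reads[ok])
  ref_chars <- strsplit(design$reference, "", fixed = TRUE)[[1]]
  counts <- matrix(0L, nrow = len, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  if (length(reads) > 0) {
    m <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                nrow = length(reads), ncol = len, byrow = TRUE)
    for (b in DNA_BASES) {
      counts[, b] <- as.integer(.colSums(m == b, nrow(m), len))
    }
  }
  out <- tibble(pos = seq_len(len), ref = ref_chars,
                A = counts[, "A"], C = counts[, "C"],
                G = counts[, "G"], T = counts[, "T"])
  out$depth <- out$A + out$C + out$G + out$T
  attr(out, "design") <- design
  attr(out, "n_reads") <- length(reads)
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("substitution_matrix", class(out))
  out
}

#' Editing frequencies along the protospacer
#'
#' Maps the substitution matrix onto protospacer positions via the
#' design's placement and reports, at each position whose reference
#' base (read on the placement strand) is the editor's substrate base,
#' the frequency of substrate-to-product conversion. Positions whose
#' reference base is not the substrate are absent from the profile
#' (absent is not 0, and stays absent through aggregation).
#' Minus-strand placements are complement-corrected. Dinucleotide
#' contexts on the editing strand are attached for
#' [context_preference()].
#'
#' @param m A `substitution_matrix`.
#' @param design The [amplicon_design()] (defaults to the one stored
#'   on `m`).
#' @param min_depth Minimum informative depth for a position to be
#'   reported (default 1; ~100 is sensible for real data).
#' @return An `editing_profile` tibble: `position` (protospacer
#'   coordinate; 0 is the R of the PAM under `cas12f_r_zero`),
#'   `genomic_pos`, `strand`, `frequency`, `depth`, `context5`,
#'   `context3`.
#' @export
window_profile <- function(m, design = attr(m, "design"), min_depth = 1L) {
  stopifnot(inherits(m, "substitution_matrix"),
            inherits(design, "amplicon_design"))
  spec <- design$spec
  pl <- design$placement
  L <- spec$protospacer_length
  positions <- if (spec$convention == "cas12f_r_zero") 0:L else 1:L
  gi <- genomic_index_at(pl[rep(1, length(positions)), , drop = FALSE],
                         positions)
  inside <- !is.na(gi) & gi >= 1 & gi <= nrow(m)
  positions <- positions[inside]; gi <- gi[inside]
  ref_chars <- m$ref
  rb <- strand_base(ref_chars, gi, pl$strand)
  keep <- rb == spec$edit_from
  positions <- positions[keep]; gi <- gi[keep]
  target_plus <- if (pl$strand == "+") spec$edit_to else {
    dna_complement(spec$edit_to)
  }
  depth <- m$depth[gi]
  freq <- ifelse(depth > 0, m[[target_plus]][gi] / depth, NA_real_)
  step <- if (pl$strand == "+") 1L else -1L
  nb <- function(g) {
    out <- rep(NA_character_, length(g))
    ok <- g >= 1 & g <= length(ref_chars)
    out[ok] <- strand_base(ref_chars, g[ok], pl$strand)
    out
  }
  ctx3 <- paste0(spec$edit_from, nb(gi + step))
  ctx5 <- paste0(nb(gi - step), spec$edit_from)
  out <- tibble(position = positions, genomic_pos = gi,
                strand = pl$strand, frequency = freq, depth = depth,
                context5 = ctx5, context3 = ctx3)
  out <- out[out$depth >= min_depth, , drop = FALSE]
  attr(out, "editor") <- spec$name
  attr(out, "edit_from") <- spec$edit_from
  attr(out, "edit_to") <- spec$edit_to
  class(out) <- c("editing_profile", class(out))
  out
}

#' Aggregate editing profiles across sites
#'
#' Per-position mean and standard error over a set of profiles (e.g.
#' one per endogenous site). A position absent from a profile (because
#' the reference base there is not the substrate) is excluded from both
#' the numerator and the denominator; `n` is reported per position.
#'
#' @param profiles A list of `editing_profile` tibbles, or one stacked
#'   tibble with a `site` column.
#' @return A tibble with columns `position`, `mean`, `sem`, `n`
#'   (`sem` is `NA` where `n == 1`).
#' @export
aggregate_profiles <- function(profiles) {
  if (is.data.frame(profiles)) {
    stacked <- profiles
    if (!"site" %in% names(stacked)) stacked$site <- 1L
  } else {
    stopifnot(length(profiles) >= 1)
    stacked <- bind_rows(lapply(seq_along(profiles), function(i) {
      p <- as_tibble(profiles[[i]]); p$site <- i; p
    }))
  }
  stacked |>
    filter(!is.na(.data$frequency)) |>
    group_by(.data$position) |>
    summarise(mean = mean(.data$frequency),
              sem = if (dplyr::n() > 1) {
                sd(.data$frequency) / sqrt(dplyr::n())
              } else NA_real_,
              n = dplyr::n(), .groups = "drop") |>
    arrange(.data$position)
}

#' Call an editing window from an aggregated profile
#'
#' The window is the set of positions whose mean frequency reaches
#' `threshold_fraction` of the maximum mean; the peak is the argmax
#' (smallest position on ties). An all-zero or empty aggregate yields
#' an empty window and no peak.
#'
#' @param agg A tibble with `position` and `mean` columns (as from
#'   [aggregate_profiles()]); a single profile with a `frequency`
#'   column is also accepted.
#' @param threshold_fraction Fraction of the maximum mean (in (0, 1],
#'   default 0.5) that defines window membership.
#' @return A list with elements `positions` (integer set) and `peak`
#'   (integer, or `NA` when the window is empty).
#' @export
call_window <- function(agg, threshold_fraction = 0.5) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  vals <- if ("mean" %in% names(agg)) agg$mean else agg$frequency
  keep <- !is.na(vals)
  vals <- vals[keep]; posn <- agg$position[keep]
  if (length(vals) == 0 || max(vals) == 0) {
    return(list(positions = integer(0), peak = NA_integer_))
  }
  mx <- max(vals)
  list(positions = sort(posn[vals >= threshold_fraction * mx]),
       peak = min(posn[vals == mx]))
}

#' Product purity at an edited position
#'
#' Among edited reads (any non-reference call) at a substrate position,
#' the fraction carrying each outcome base — e.g. how many C edits are
#' C-to-T rather than C-to-G or C-to-A. Fractions sum to 1 when any
#' edited read exists; with zero edited reads the result is flagged
#' undefined (`defined` attribute `FALSE`, fractions `NA`), never
#' silently 0.
#'
#' @param m A `substitution_matrix`.
#' @param position 1-based reference position; its reference base must
#'   be the editor's substrate base on the placement strand.
#' @param design The [amplicon_design()] (defaults to the one stored
#'   on `m`).
#' @return A tibble with one row per outcome base: `outcome` (e.g.
#'   `"C>T"`, in editing-strand terms), `count`, `fraction`; attributes
#'   `n_edited`, `defined`, `position`.
#' @export
product_purity <- function(m, position, design = attr(m, "design")) {
  stopifnot(inherits(m, "substitution_matrix"))
  spec <- design$spec
  strand <- design$placement$strand
  rb <- strand_base(m$ref, position, strand)
  if (rb != spec$edit_from) {
    abort(sprintf(
      "position %d has reference base %s on the editing strand, not %s",
      position, rb, spec$edit_from), class = "mbescope_usage_error")
  }
  ref_plus <- m$ref[position]
  outcome_plus <- setdiff(DNA_BASES, ref_plus)
  counts <- vapply(outcome_plus, function(b) as.numeric(m[[b]][position]),
                   numeric(1), USE.NAMES = FALSE)
  outcome_strand <- if (strand == "+") outcome_plus else {
    dna_complement(outcome_plus)
  }
  n_edited <- sum(counts)
  out <- tibble(outcome = paste0(spec$edit_from, ">", outcome_strand),
                count = as.integer(counts),
                fraction = if (n_edited > 0) counts / n_edited else NA_real_)
  out <- arrange(out, .data$outcome)
  attr(out, "n_edited") <- as.integer(n_edited)
  attr(out, "defined") <- n_edited > 0
  attr(out, "position") <- as.integer(position)
  out
}

#' Joint allele outcomes over the editable window positions
#'
#' Tabulates reads by their joint base states at every editable window
#' position (activity-window positions whose reference base on the
#' editing strand is the substrate base), and reports the proportion of
#' the desired allele among all reads and among edited reads. Reads
#' with an `N` at any window position are excluded and counted.
#'
#' The desired allele carries the desired base at each position named
#' in `desired` and the unedited substrate base at every other editable
#' position.
#'
#' @param reads Character vector of reads (same orientation as the
#'   reference).
#' @param design An [amplicon_design()].
#' @param desired Named character vector mapping protospacer position
#'   to desired base (editing-strand, normally the product base), e.g.
#'   `c("3" = "T")`.
#' @return An `allele_table`: a list with `table` (tibble of `allele`,
#'   per-position base columns, `count`, `proportion`, `edited`,
#'   `is_reference`, `is_desired`), `desired_among_all`,
#'   `desired_among_edited`, `n_reads`, `n_excluded`, `positions`.
#' @export
allele_outcomes <- function(reads, design, desired) {
  stopifnot(inherits(design, "amplicon_design"))
  spec <- design$spec
  pl <- design$placement
  win <- spec$activity_window
  gi <- genomic_index_at(pl[rep(1, length(win)), , drop = FALSE], win)
  ref_chars <- strsplit(design$reference, "", fixed = TRUE)[[1]]
  editable <- !is.na(gi) & gi >= 1 & gi <= length(ref_chars) &
    strand_base(ref_chars, gi, pl$strand) == spec$edit_from
  win <- win[editable]; gi <- gi[editable]
  if (length(win) == 0) {
    abort("no editable window position on this design",
          class = "mbescope_usage_error")
  }
  dpos <- as.integer(names(desired))
  if (!all(dpos %in% win)) {
    abort("desired positions must be editable window positions",
          class = "mbescope_usage_error")
  }

  len <- nchar(design$reference)
  reads <- toupper(reads[nchar(reads) == len])
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                nrow = length(reads), ncol = len, byrow = TRUE)
  bases <- mat[, gi, drop = FALSE]
  if (pl$strand == "-") bases[] <- dna_complement(bases)
  has_n <- rowSums(!matrix(bases %in% DNA_BASES, nrow = nrow(bases))) > 0
  n_excluded <- sum(has_n)
  bases <- bases[!has_n, , drop = FALSE]

  allele <- apply(bases, 1, paste, collapse = "")
  tab <- table(allele)
  ord <- order(-as.integer(tab), names(tab))
  allele_str <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  split_mat <- do.call(rbind, strsplit(allele_str, "", fixed = TRUE))
  ref_allele <- strrep(spec$edit_from, length(win))
  desired_vec <- setNames(rep(spec$edit_from, length(win)),
                          as.character(win))
  desired_vec[as.character(dpos)] <- desired
  desired_allele <- paste(desired_vec[as.character(win)], collapse = "")

  out_tab <- tibble(allele = allele_str, count = counts,
                    proportion = counts / sum(counts),
                    edited = allele_str != ref_allele,
                    is_reference = allele_str == ref_allele,
                    is_desired = allele_str == desired_allele)
  for (k in seq_along(win)) {
    out_tab[[paste0("pos", win[k])]] <- split_mat[, k]
  }
  n_edited <- sum(out_tab$count[out_tab$edited])
  res <- list(
    table = out_tab,
    desired_among_all = sum(out_tab$count[out_tab$is_desired]) /
      sum(out_tab$count),
    desired_among_edited = if (n_edited > 0) {
      sum(out_tab$count[out_tab$is_desired & out_tab$edited]) / n_edited
    } else NA_real_,
    n_reads = sum(out_tab$count),
    n_excluded = n_excluded,
    positions = win,
    desired_allele = desired_allele
  )
  class(res) <- "allele_table"
  res
}

#' @exportS3Method base::print
print.allele_table <- function(x, ...) {
  cat(sprintf("<allele_table> %d reads over positions {%s} (%d excluded for N)\n",
              x$n_reads, paste(x$positions, collapse = ","), x$n_excluded))
  cat(sprintf("  desired allele %s: %.3f of all reads, %s of edited reads\n",
              x$desired_allele, x$desired_among_all,
              ifelse(is.na(x$desired_among_edited), "undefined",
                     sprintf("%.3f", x$desired_among_edited))))
  print(x$table, n = 10)
  invisible(x)
}

#' @export
tidy.allele_table <- function(x, ...) x$table

#' @export
glance.allele_table <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_excluded = x$n_excluded,
         desired_among_all = x$desired_among_all,
         desired_among_edited = x$desired_among_edited)
}

#' Sequence-context preference of an editor
#'
#' Groups per-position editing frequencies by dinucleotide context on
#' the editing strand — 3'-neighbour classes (substrate base first,
#' e.g. CA/CT/CC/CG for a cytosine editor) or 5'-neighbour classes
#' (substrate base second, e.g. AC/CC/GC/TC) — and reports the mean
#' frequency, observation count and induced ranking per class. Exact
#' ties share a rank (no arbitrary order); classes with zero
#' observations are absent.
#'
#' @param profiles An `editing_profile`, a list of them, or a stacked
#'   tibble with a `site` column.
#' @param side `"three_prime"` (default) or `"five_prime"`.
#' @return A tibble with columns `context`, `side`, `n`, `mean_freq`,
#'   `rank`, sorted by decreasing mean frequency.
#' @export
context_preference <- function(profiles,
                               side = c("three_prime", "five_prime")) {
  side <- match.arg(side)
  if (is.data.frame(profiles)) {
    stacked <- as_tibble(profiles)
  } else {
    stacked <- bind_rows(lapply(profiles, as_tibble))
  }
  col <- if (side == "three_prime") "context3" else "context5"
  stacked <- stacked[!is.na(stacked$frequency) & !is.na(stacked[[col]]), ]
  out <- stacked |>
    group_by(context = .data[[col]]) |>
    summarise(n = dplyr::n(), mean_freq = mean(.data$frequency),
              .groups = "drop") |>
    arrange(desc(.data$mean_freq), .data$context)
  out$side <- side
  out$rank <- dplyr::min_rank(desc(out$mean_freq))
  select(out, "context", "side", "n", "mean_freq", "rank")
}

#' On-to-off-target editing ratio
#'
#' Ratio of on-target to off-target editing frequency, with zero
#' off-target edits floored at one read (`1/off_depth`) so the ratio
#' stays finite; a flag records when the floor was applied.
#'
#' @param on_freq,off_freq Editing frequencies in \\[0, 1\\]
#'   (vectorised).
#' @param off_depth Informative depth at the off-target site (> 0).
#' @return A tibble with columns `on_freq`, `off_freq`, `off_depth`,
#'   `ratio`, `floored`.
#' @export
on_off_ratio <- function(on_freq, off_freq, off_depth) {
  if (any(off_depth <= 0)) {
    abort("off_depth must be positive", class = "mbescope_usage_error")
  }
  if (any(on_freq < 0 | on_freq > 1 | off_freq < 0 | off_freq > 1)) {
    abort("frequencies must lie in [0, 1]", class = "mbescope_usage_error")
  }
  floor_ <- 1 / off_depth
  eff <- pmax(off_freq, floor_)
  tibble(on_freq = on_freq, off_freq = off_freq,
         off_depth = as.integer(off_depth),
         ratio = on_freq / eff, floored = off_freq < floor_)
}

#' R-loop site statistics
#'
#' For a window of an orthogonal R-loop assay amplicon: the sum of
#' per-position conversion frequencies over every position whose
#' reference base is `base` (C-to-T for cytosines, A-to-G for
#' adenines), and the maximum per-position frequency with its position
#' (smallest coordinate on ties). A window containing no such base
#' reports sum 0 and an undefined-flagged maximum.
#'
#' @param m A `substitution_matrix` (plus-strand amplicon).
#' @param window Length-2 integer vector `c(start, end)`, 1-based
#'   inclusive, within the matrix.
#' @param base `"C"` or `"A"`.
#' @return A one-row tibble: `base`, `n_positions`, `sum_freq`,
#'   `max_freq`, `max_pos`, `defined`.
#' @export
rloop_stats <- function(m, window, base = c("C", "A")) {
  base <- match.arg(base)
  stopifnot(length(window) == 2, window[1] >= 1, window[2] <= nrow(m),
            window[1] <= window[2])
  outcome <- if (base == "C") "T" else "G"
  idx <- window[1]:window[2]
  idx <- idx[m$ref[idx] == base]
  if (length(idx) == 0) {
    return(tibble(base = base, n_positions = 0L, sum_freq = 0,
                  max_freq = NA_real_, max_pos = NA_integer_,
                  defined = FALSE))
  }
  freq <- ifelse(m$depth[idx] > 0, m[[outcome]][idx] / m$depth[idx], 0)
  mx <- max(freq)
  tibble(base = base, n_positions = length(idx), sum_freq = sum(freq),
         max_freq = mx, max_pos = as.integer(min(idx[freq == mx])),
         defined = TRUE)
}
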