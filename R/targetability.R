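# Variant targetability: can a given editor revert a pathogenic SNV,
# and can it do so precisely (no same-chemistry bystander in the
# window)?
#
# Correction is physical: the molecule scanned for PAM placements is
# the ALT-carrying flank (the allele actually present in the patient
# genome), because a variant may create or destroy its own PAM.  A
# variant is correctable by an editor iff, on either strand, the alt
# base reads as the editor's substrate base at an activity-window
# position of some placement and the edit product equals the reference
# allele.

#' Build a variant table
#'
#' Constructs the tibble of SNVs consumed by the classifiers. Each
#' variant carries a flanking sequence window centred on the variant
#' site; the flank holds the REFERENCE allele at its centre (the ALT
#' allele is substituted internally when scanning for placements).
#'
#' @param contig,pos,ref,alt,flank Vectors (recycled) of contig name,
#'   1-based position, reference and alternate base, and flank
#'   sequence. The flank must have odd length with `ref` at its
#'   central base.
#' @param label Optional per-variant label (e.g. `"Pathogenic"`).
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `label`, `flank`.
#' @export
variant_table <- function(contig, pos, ref, alt, flank, label = NA_character_) {
  v <- tibble(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
              label = label, flank = toupper(flank))
  ctr <- (nchar(v$flank) + 1L) %/% 2L
  central <- substr(v$flank, ctr, ctr)
  if (any(nchar(v$flank) %% 2L == 0L)) {
    abort("flanks must have odd length (variant at the central base)",
          class = "mbescope_validation_error")
  }
  if (any(central != v$ref)) {
    abort("ref does not equal the flank's central base",
          class = "mbescope_validation_error")
  }
  if (any(v$ref == v$alt) || any(nchar(v$ref) != 1L | nchar(v$alt) != 1L)) {
    abort("variants must be SNVs with ref != alt",
          class = "mbescope_validation_error")
  }
  v
}

# Classify a single variant against a spec.  Returns a list with the
# verdicts and a tibble of qualifying placements.
classify_one <- function(flank, ref, alt, spec,
                         bystander_scope = "activity_window") {
  # chemistry shortcut: which strands could even perform alt -> ref?
  plus_ok <- alt == spec$edit_from && spec$edit_to == ref
  minus_ok <- dna_complement(alt) == spec$edit_from &&
    dna_complement(spec$edit_to) == ref
  empty <- tibble(strand = character(), pam_start = integer(),
                  pam_end = integer(), anchor = integer(),
                  proto_start = integer(), proto_end = integer(),
                  position = integer(), bystanders = list(),
                  n_bystanders = integer(), in_precision = logical())
  if (!plus_ok && !minus_ok) {
    return(list(correctable = FALSE, precise = FALSE, placements = empty))
  }

  width <- nchar(flank)
  center <- (width + 1L) %/% 2L
  need <- spec$protospacer_length + nchar(spec$pam) - 1L
  if (center - 1L < need || width - center < need) {
    abort(sprintf(
      "flank too short to determine targetability (need >= %d nt each side, have %d/%d)",
      need, center - 1L, width - center),
      class = "mbescope_undeterminable_error")
  }

  alt_flank <- set_base(flank, center, alt)
  chars <- strsplit(alt_flank, "", fixed = TRUE)[[1]]
  pl <- find_pam_sites(alt_flank, spec)
  if (nrow(pl) == 0) {
    return(list(correctable = FALSE, precise = FALSE, placements = empty))
  }
  pos <- protospacer_position(pl, center)
  keep <- !is.na(pos) & pos %in% spec$activity_window &
    ifelse(pl$strand == "+", plus_ok, minus_ok)
  pl <- pl[keep, , drop = FALSE]
  pos <- pos[keep]
  if (nrow(pl) == 0) {
    return(list(correctable = FALSE, precise = FALSE, placements = empty))
  }

  scope <- if (bystander_scope == "precision_window") {
    spec$precision_window
  } else {
    spec$activity_window
  }
  bys <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    others <- setdiff(spec$activity_window, pos[i])
    if (length(others) == 0) {
      bys[[i]] <- integer(0)
      next
    }
    gi <- genomic_index_at(pl[rep(i, length(others)), , drop = FALSE], others)
    b <- strand_base(chars, gi, pl$strand[i])
    bys[[i]] <- sort(others[b == spec$edit_from])
  }
  in_prec <- pos %in% spec$precision_window
  scope_clear <- vapply(bys, function(b) !any(b %in% scope), logical(1))

  placements <- tibble(
    strand = pl$strand, pam_start = pl$pam_start, pam_end = pl$pam_end,
    anchor = pl$anchor, proto_start = pl$proto_start,
    proto_end = pl$proto_end, position = pos, bystanders = bys,
    n_bystanders = vapply(bys, length, integer(1)),
    in_precision = in_prec
  )
  list(correctable = TRUE,
       precise = any(in_prec & scope_clear),
       placements = placements)
}

#' Classify variants as correctable by an editor
#'
#' A variant is correctable iff the alt allele, read on either strand,
#' is the editor's substrate base at an activity-window position of
#' some PAM placement on the alt-carrying flank, such that the edit
#' restores the reference allele. All qualifying placements are
#' returned with their predicted bystanders (other substrate bases in
#' the activity window under that placement).
#'
#' A flank too short to rule placements in or out raises an explicit
#' "undeterminable" error rather than silently returning `FALSE`; with
#' the default 30-nt flank radius every PAM/protospacer geometry is
#' covered.
#'
#' @param variants A tibble from [variant_table()] (columns `contig`,
#'   `pos`, `ref`, `alt`, `flank`).
#' @param spec A [base_editor_spec()].
#' @return The input tibble with added columns `editor`, `correctable`
#'   (logical) and `placements` (list-column of per-placement tibbles
#'   with protospacer `position`, `bystanders` and `in_precision`).
#' @export
classify_correctable <- function(variants, spec) {
  res <- pmap(list(variants$flank, variants$ref, variants$alt),
              classify_one, spec = spec)
  variants$editor <- spec$name
  variants$correctable <- map_lgl(res, `[[`, "correctable")
  variants$placements <- map(res, `[[`, "placements")
  variants
}

#' Classify variants as precisely correctable
#'
#' Extends [classify_correctable()] with the precision verdict: a
#' variant is precisely correctable iff some qualifying placement puts
#' the target inside the precision window AND no bystander substrate
#' base occupies any other scoped window position under that placement.
#' The default scope is the full activity window (the strictest reading
#' of single-base resolution); set
#' `bystander_scope = "precision_window"` to tolerate bystanders
#' outside the precision window.
#'
#' @inheritParams classify_correctable
#' @param bystander_scope `"activity_window"` (default) or
#'   `"precision_window"`: where a bystander disqualifies precision.
#' @return The input tibble with added columns `editor`, `correctable`,
#'   `precise` and `placements`. `precise` implies `correctable`.
#' @export
classify_precise <- function(variants, spec,
                             bystander_scope = c("activity_window",
                                                 "precision_window")) {
  bystander_scope <- match.arg(bystander_scope)
  res <- pmap(list(variants$flank, variants$ref, variants$alt),
              classify_one, spec = spec, bystander_scope = bystander_scope)
  variants$editor <- spec$name
  variants$correctable <- map_lgl(res, `[[`, "correctable")
  variants$precise <- map_lgl(res, `[[`, "precise")
  variants$placements <- map(res, `[[`, "placements")
  variants
}

#' Design sgRNA placements to install a mutation
#'
#' Enumerates every placement of the editor that puts the target base
#' at an activity-window position of a PAM placement on `seq` (the
#' reference molecule, since installation edits the wild-type allele)
#' such that editing converts `ref` to `alt`. Candidates are ranked by
#' (1) target inside the precision window, (2) fewer bystanders,
#' (3) target at a preferred position, (4) smaller position number.
#'
#' @param seq DNA string (reference sequence).
#' @param pos 1-based position of the target base within `seq`.
#' @param ref,alt Current and desired base at `pos`.
#' @param spec A [base_editor_spec()].
#' @param contig Contig name recorded in the output.
#' @return A ranked tibble of candidate placements with columns
#'   `rank`, `strand`, `pam_start`, `pam_end`, `position`,
#'   `bystanders` (list), `n_bystanders`, `in_precision`,
#'   `in_preferred`. Empty (zero rows) when no PAM is in range.
#' @export
design_installation <- function(seq, pos, ref, alt, spec, contig = "seq") {
  chars <- seq_chars(seq)
  pos <- as.integer(pos)
  if (chars[pos] != ref) {
    abort(sprintf("sequence has %s at position %d, not %s",
                  chars[pos], pos, ref), class = "mbescope_usage_error")
  }
  plus_ok <- ref == spec$edit_from && alt == spec$edit_to
  minus_ok <- dna_complement(ref) == spec$edit_from &&
    dna_complement(alt) == spec$edit_to
  if (!plus_ok && !minus_ok) {
    abort(sprintf(
      paste0("change %s>%s is incompatible with %s chemistry: requires ",
             "%s>%s on the plus strand or %s>%s on the minus strand"),
      ref, alt, spec$name, spec$edit_from, spec$edit_to,
      dna_complement(spec$edit_from), dna_complement(spec$edit_to)),
      class = "mbescope_usage_error")
  }
  pl <- find_pam_sites(seq, spec, contig = contig)
  ppos <- protospacer_position(pl, pos)
  keep <- !is.na(ppos) & ppos %in% spec$activity_window &
    ifelse(pl$strand == "+", plus_ok, minus_ok)
  pl <- pl[keep, , drop = FALSE]
  ppos <- ppos[keep]
  if (nrow(pl) == 0) {
    return(tibble(rank = integer(), strand = character(),
                  pam_start = integer(), pam_end = integer(),
                  position = integer(), bystanders = list(),
                  n_bystanders = integer(), in_precision = logical(),
                  in_preferred = logical()))
  }
  bys <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    others <- setdiff(spec$activity_window, ppos[i])
    if (length(others) == 0) { bys[[i]] <- integer(0); next }
    gi <- genomic_index_at(pl[rep(i, length(others)), , drop = FALSE], others)
    ok <- !is.na(gi) & gi >= 1 & gi <= length(chars)
    b <- strand_base(chars, gi[ok], pl$strand[i])
    bys[[i]] <- sort(others[ok][b == spec$edit_from])
  }
  out <- tibble(
    strand = pl$strand, pam_start = pl$pam_start, pam_end = pl$pam_end,
    position = ppos, bystanders = bys,
    n_bystanders = vapply(bys, length, integer(1)),
    in_precision = ppos %in% spec$precision_window,
    in_preferred = ppos %in% (spec$preferred_positions %||% integer(0))
  )
  out <- arrange(out, desc(.data$in_precision), .data$n_bystanders,
                 desc(.data$in_preferred), .data$position)
  out$rank <- seq_len(nrow(out))
  select(out, "rank", dplyr::everything())
}

#' Cohort targetability fractions by editor and transition class
#'
#' Runs [classify_precise()] for each named editor over a variant
#' cohort and tabulates, per editor and per variant transition class
#' (ref>alt on the reported plus strand), the fraction of variants
#' that are correctable and precisely correctable. Numerators and
#' denominators are emitted alongside the fractions so every number is
#' auditable; classes with zero variants report `NA` fractions
#' (undefined, not 0). The four transition classes `A>G`, `C>T`,
#' `G>A`, `T>C` are always present, other observed classes are
#' appended, and an `all` row summarises the whole cohort.
#'
#' @param variants A tibble from [variant_table()]; must be non-empty.
#' @param registry An `editor_registry`.
#' @param editors Character vector of editor names to evaluate.
#' @param bystander_scope Passed to [classify_precise()].
#' @return A tibble with columns `editor`, `class`, `n`,
#'   `n_correctable`, `n_precise`, `frac_correctable`, `frac_precise`.
#' @export
cohort_fractions <- function(variants, registry, editors,
                             bystander_scope = "activity_window") {
  if (nrow(variants) == 0) {
    abort("empty cohort", class = "mbescope_usage_error")
  }
  canonical <- c("A>G", "C>T", "G>A", "T>C")
  per_editor <- lapply(editors, function(nm) {
    spec <- editor(registry, nm)
    cls <- classify_precise(variants, spec,
                            bystander_scope = bystander_scope)
    cls$class <- paste0(cls$ref, ">", cls$alt)
    by_class <- cls |>
      group_by(.data$class) |>
      summarise(n = dplyr::n(),
                n_correctable = sum(.data$correctable),
                n_precise = sum(.data$precise), .groups = "drop")
    missing_cls <- setdiff(canonical, by_class$class)
    if (length(missing_cls) > 0) {
      by_class <- bind_rows(by_class,
                            tibble(class = missing_cls, n = 0L,
                                   n_correctable = 0L, n_precise = 0L))
    }
    all_row <- tibble(class = "all", n = nrow(cls),
                      n_correctable = sum(cls$correctable),
                      n_precise = sum(cls$precise))
    out <- bind_rows(by_class, all_row)
    out$editor <- nm
    out
  })
  out <- bind_rows(per_editor)
  out$frac_correctable <- ifelse(out$n > 0, out$n_correctable / out$n, NA_real_)
  out$frac_precise <- ifelse(out$n > 0, out$n_precise / out$n, NA_real_)
  cls_order <- c(canonical, setdiff(sort(unique(out$class)),
                                    c(canonical, "all")), "all")
  out$class <- factor(out$class, levels = cls_order)
  out <- arrange(out, .data$editor, .data$class)
  out$class <- as.character(out$class)
  select(out, "editor", "class", "n", "n_correctable", "n_precise",
         "frac_correctable", "frac_precise")
}
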