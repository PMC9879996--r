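# Formal editor specifications and the packaged registry.
#
# Everything downstream (scanning, targetability, quantification) is
# parameterised by a base_editor_spec: the chemistry (A->G or C->T), the
# PAM and its side, the protospacer coordinate convention, and the
# activity / precision windows as explicit integer sets.  Windows are
# sets, not ranges, so non-contiguous windows (e.g. the CL-terminal
# fusion ABE with a peak at position 13 plus scattered flanking
# activity) are representable.

#' Construct a base editor specification
#'
#' A `base_editor_spec` formalises one base editor as data: its
#' chemistry (`edit_from` to `edit_to`, either A to G or C to T), PAM
#' pattern and side, protospacer coordinate convention, and editing
#' windows expressed as explicit sets of protospacer positions.
#'
#' Two conventions are supported. Under `cas12f_r_zero` (hypercompact
#' Cas12f editors) the PAM (e.g. `TTTR`) lies 5' of the protospacer and
#' the final PAM base -- the R -- is position 0, so the first protospacer
#' base is position 1. Under `spcas9_pam_distal` (nCas9-based editors,
#' PAM `NGG` 3' of the protospacer) positions run 1..20 from the
#' PAM-distal end, the usual SpCas9 numbering.
#'
#' @param name Editor name (unique within a registry).
#' @param edit_from,edit_to Substrate and product base on the targeted
#'   strand: `"A"`/`"G"` for adenine editors, `"C"`/`"T"` for cytosine
#'   editors.
#' @param pam IUPAC pattern, e.g. `"TTTR"` or `"NGG"`.
#' @param pam_side `"five_prime"` or `"three_prime"`, relative to the
#'   protospacer.
#' @param convention `"cas12f_r_zero"` or `"spcas9_pam_distal"`.
#' @param activity_window Integer set of protospacer positions with
#'   appreciable editing.
#' @param precision_window Subset of `activity_window` counted as
#'   precise placements; defaults to the full activity window.
#' @param preferred_positions Optional subset of `activity_window` with
#'   the strongest activity.
#' @param context_ranking Optional list with elements `three_prime`
#'   and/or `five_prime`, each an ordered list of character vectors of
#'   dinucleotide context classes (ties share a tier).
#' @param provenance Free-text note recording where the windows were
#'   read from; mandatory for registry entries.
#' @param protospacer_length Protospacer length in nt (default 20).
#' @return An object of class `base_editor_spec`.
#' @examples
#' base_editor_spec("toyABE", "A", "G", "TTTR", "five_prime",
#'                  "cas12f_r_zero", activity_window = 3:4)
#' @export
base_editor_spec <- function(name, edit_from, edit_to, pam, pam_side,
                             convention,
                             activity_window,
                             precision_window = activity_window,
                             preferred_positions = NULL,
                             context_ranking = NULL,
                             provenance = "",
                             protospacer_length = 20L) {
  chem_ok <- (edit_from == "A" && edit_to == "G") ||
    (edit_from == "C" && edit_to == "T")
  if (!chem_ok) {
    abort(sprintf("editor '%s': chemistry must be A->G or C->T, got %s->%s",
                  name, edit_from, edit_to),
          class = "mbescope_validation_error")
  }
  pam_side <- match.arg(pam_side, c("five_prime", "three_prime"))
  convention <- match.arg(convention, c("cas12f_r_zero", "spcas9_pam_distal"))
  pam_chars <- seq_chars(pam, what = sprintf("editor '%s': pam", name))

  activity_window <- sort(unique(as.integer(activity_window)))
  precision_window <- sort(unique(as.integer(precision_window)))
  if (!all(precision_window %in% activity_window)) {
    abort(sprintf("editor '%s': precision_window is not a subset of activity_window",
                  name), class = "mbescope_validation_error")
  }
  if (!is.null(preferred_positions)) {
    preferred_positions <- sort(unique(as.integer(preferred_positions)))
    if (!all(preferred_positions %in% activity_window)) {
      abort(sprintf("editor '%s': preferred_positions is not a subset of activity_window",
                    name), class = "mbescope_validation_error")
    }
  }
  L <- as.integer(protospacer_length)
  if (convention == "cas12f_r_zero" &&
      any(activity_window < 1L | activity_window > L)) {
    abort(sprintf("editor '%s': cas12f_r_zero window positions must lie in 1..%d (0 is the R of the PAM)",
                  name, L), class = "mbescope_validation_error")
  }
  if (convention == "spcas9_pam_distal" &&
      any(activity_window < 1L | activity_window > L)) {
    abort(sprintf("editor '%s': spcas9_pam_distal window positions must lie in 1..%d",
                  name, L), class = "mbescope_validation_error")
  }

  structure(
    list(name = name, edit_from = edit_from, edit_to = edit_to,
         pam = paste(pam_chars, collapse = ""), pam_side = pam_side,
         convention = convention,
         activity_window = activity_window,
         precision_window = precision_window,
         preferred_positions = preferred_positions,
         context_ranking = context_ranking,
         provenance = provenance,
         protospacer_length = L),
    class = "base_editor_spec"
  )
}

#' @exportS3Method base::print
print.base_editor_spec <- function(x, ...) {
  cat(sprintf("<base_editor_spec> %s\n", x$name))
  cat(sprintf("  %s->%s, PAM %s (%s, %s)\n", x$edit_from, x$edit_to,
              x$pam, x$pam_side, x$convention))
  cat(sprintf("  activity window: %s%d..%s%d {%s}\n", x$edit_from,
              min(x$activity_window), x$edit_from, max(x$activity_window),
              paste(x$activity_window, collapse = ",")))
  cat(sprintf("  precision window: {%s}\n",
              paste(x$precision_window, collapse = ",")))
  if (!is.null(x$preferred_positions)) {
    cat(sprintf("  preferred: {%s}\n",
                paste(x$preferred_positions, collapse = ",")))
  }
  invisible(x)
}

#' Load an editor registry
#'
#' Reads a registry of [base_editor_spec()] entries from the documented
#' JSON format. With `path = NULL` the registry packaged with mbescope
#' is loaded; it covers the Cas12f-derived miniature adenine and
#' cytosine editors, the nCas9 1249-insertion constructs, and two
#' "union" pseudo-editors (`miniABE-any`, `miniCBE-any`) whose windows
#' are the union of the functional miniature editors' windows (A2-A18
#' and C3-C20), used for cohort-level targetability scans.
#'
#' Each JSON entry must carry a non-empty `provenance` string saying
#' where its windows were read from, so every window is auditable.
#'
#' @param path Path to a registry JSON file, or `NULL` for the packaged
#'   default.
#' @return An `editor_registry`: a named list of `base_editor_spec`
#'   objects.
#' @examples
#' reg <- load_registry()
#' names(reg)
#' reg[["N-dRRAABE-TadA*(82G)"]]$activity_window
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "editor_registry.json",
                        package = "mbescope", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- raw$editors %||% abort("registry file has no 'editors' array",
                                    class = "mbescope_validation_error")
  specs <- lapply(entries, function(e) {
    prov <- e$provenance %||% ""
    if (!nzchar(prov)) {
      abort(sprintf("registry entry '%s': provenance is mandatory",
                    e$name %||% "<unnamed>"),
            class = "mbescope_validation_error")
    }
    ctx <- e$context_ranking
    if (!is.null(ctx)) {
      ctx <- lapply(ctx, function(side) lapply(side, function(tier) {
        unlist(tier, use.names = FALSE)
      }))
    }
    spec <- base_editor_spec(
      name = e$name, edit_from = e$edit_from, edit_to = e$edit_to,
      pam = e$pam, pam_side = e$pam_side, convention = e$convention,
      activity_window = unlist(e$activity_window),
      precision_window = unlist(e$precision_window %||% e$activity_window),
      preferred_positions = if (!is.null(e$preferred_positions)) {
        unlist(e$preferred_positions)
      },
      context_ranking = ctx,
      provenance = prov,
      protospacer_length = e$protospacer_length %||% 20L
    )
    contiguous_declared <- isTRUE(e$contiguous %||% TRUE)
    w <- spec$activity_window
    if (contiguous_declared && length(w) > 1 &&
        !identical(w, seq(min(w), max(w)))) {
      abort(sprintf("registry entry '%s': window declared contiguous but has gaps",
                    spec$name), class = "mbescope_validation_error")
    }
    spec
  })
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate editor names in registry: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
          class = "mbescope_validation_error")
  }
  structure(setNames(specs, nm), class = "editor_registry", source = path)
}

#' Serialise an editor registry to JSON
#'
#' Writes a registry in the same JSON dialect that [load_registry()]
#' reads, so `load_registry(write_registry(reg, f))` round-trips.
#'
#' @param registry An `editor_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "editor_registry"))
  entries <- lapply(unname(registry), function(s) {
    e <- list(name = s$name, edit_from = s$edit_from, edit_to = s$edit_to,
              pam = s$pam, pam_side = s$pam_side, convention = s$convention,
              activity_window = s$activity_window,
              precision_window = s$precision_window)
    if (!is.null(s$preferred_positions)) {
      e$preferred_positions <- s$preferred_positions
    }
    if (!is.null(s$context_ranking)) e$context_ranking <- s$context_ranking
    w <- s$activity_window
    if (length(w) > 1 && !identical(w, seq(min(w), max(w)))) {
      e$contiguous <- FALSE
    }
    e$provenance <- s$provenance
    e$protospacer_length <- s$protospacer_length
    e
  })
  jsonlite::write_json(
    list(format = "mbescope-editor-registry", version = 1L,
         editors = entries),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' Look up one editor in a registry
#'
#' @param registry An `editor_registry` from [load_registry()].
#' @param name Editor name.
#' @return A `base_editor_spec`.
#' @export
editor <- function(registry, name) {
  stopifnot(inherits(registry, "editor_registry"))
  spec <- registry[[name]]
  if (is.null(spec)) {
    abort(sprintf("no editor named '%s' in registry (available: %s)",
                  name, paste(names(registry), collapse = ", ")),
          class = "mbescope_usage_error")
  }
  spec
}

#' Edit chemistry seen from the opposite strand
#'
#' Strand algebra used by the scanner and classifier: an A-to-G editor
#' acting on the minus strand appears as T-to-C on the plus strand, and
#' a C-to-T editor as G-to-A. Applying the operation twice returns the
#' original chemistry.
#'
#' @param spec A `base_editor_spec`, or a length-2 character vector
#'   `c(from, to)`.
#' @return Named character vector `c(from = , to = )`.
#' @examples
#' complement_edit(base_editor_spec("abe", "A", "G", "TTTR",
#'   "five_prime", "cas12f_r_zero", 2:4))
#' @export
complement_edit <- function(spec) {
  if (inherits(spec, "base_editor_spec")) {
    from <- spec$edit_from; to <- spec$edit_to
  } else {
    from <- spec[[1]]; to <- spec[[2]]
  }
  c(from = dna_complement(from), to = dna_complement(to))
}

#' @exportS3Method base::print
print.editor_registry <- function(x, ...) {
  cat(sprintf("<editor_registry> %d editors (%s)\n", length(x),
              attr(x, "source") %||% "in-memory"))
  print(tidy(x), n = length(x))
  invisible(x)
}

#' Tidy an editor registry into a tibble
#'
#' @param x An `editor_registry`.
#' @param ... Unused.
#' @return A tibble with one row per editor; window columns are
#'   list-columns of integer vectors.
#' @export
tidy.editor_registry <- function(x, ...) {
  tibble(
    name = names(x),
    edit_from = vapply(x, `[[`, character(1), "edit_from"),
    edit_to = vapply(x, `[[`, character(1), "edit_to"),
    pam = vapply(x, `[[`, character(1), "pam"),
    pam_side = vapply(x, `[[`, character(1), "pam_side"),
    convention = vapply(x, `[[`, character(1), "convention"),
    activity_window = lapply(x, `[[`, "activity_window"),
    precision_window = lapply(x, `[[`, "precision_window"),
    preferred_positions = lapply(x, `[[`, "preferred_positions"),
    provenance = vapply(x, `[[`, character(1), "provenance")
  )
}
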