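# Hard filtering of variant-call records (RNA-editing analysis) and
# edit-class counting.
#
# The filter is the disjunction
#   QUAL < 25 || MQ < 20.0 || QD < 2.0 || FS > 30.0 || DP < 20
# applied to caller output records; a record fails iff any clause
# holds, so boundary values (QUAL = 25, MQ = 20, QD = 2, FS = 30,
# DP = 20) pass.  No alignment or calling is performed here.

#' Hard-filter thresholds
#'
#' The five-clause disjunction used to drop low-confidence RNA-seq
#' variant calls. All thresholds are strict-inequality bounds:
#' a record fails when `QUAL < qual_min`, `MQ < mq_min`,
#' `QD < qd_min`, `FS > fs_max` or `DP < dp_min`.
#'
#' @param qual_min Minimum variant quality (default 25).
#' @param mq_min Minimum RMS mapping quality (default 20).
#' @param qd_min Minimum quality-by-depth (default 2).
#' @param fs_max Maximum Fisher-strand phred score (default 30).
#' @param dp_min Minimum read depth (default 20).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(qual_min = 25, mq_min = 20, qd_min = 2,
                              fs_max = 30, dp_min = 20) {
  t <- list(qual_min = qual_min, mq_min = mq_min, qd_min = qd_min,
            fs_max = fs_max, dp_min = dp_min)
  if (!all(vapply(t, is.finite, logical(1)))) {
    abort("all thresholds must be finite",
          class = "mbescope_validation_error")
  }
  structure(t, class = "filter_thresholds")
}

#' Apply the hard filter to variant-call records
#'
#' Evaluates the five-clause disjunction on each record and reports,
#' per record, the pass verdict and the list of failed clauses. A
#' missing (NA) field fails the record with reason `"missing:<field>"`.
#'
#' @param records A tibble with columns `QUAL`, `MQ`, `QD`, `FS`,
#'   `DP` (as read by [read_called_variants()]).
#' @param thresholds A [filter_thresholds()].
#' @return The input tibble with added columns `pass` (logical) and
#'   `failed` (list-column of clause names among `"QUAL"`, `"MQ"`,
#'   `"QD"`, `"FS"`, `"DP"`, `"missing:<field>"`).
#' @examples
#' recs <- tibble::tibble(QUAL = c(30, 24.9), MQ = 25, QD = 3,
#'                        FS = 10, DP = 25)
#' hard_filter(recs, filter_thresholds())
#' @export
hard_filter <- function(records, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  fields <- c("QUAL", "MQ", "QD", "FS", "DP")
  missing_cols <- setdiff(fields, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records lack columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "mbescope_usage_error")
  }
  clause <- list(
    QUAL = records$QUAL < thresholds$qual_min,
    MQ   = records$MQ < thresholds$mq_min,
    QD   = records$QD < thresholds$qd_min,
    FS   = records$FS > thresholds$fs_max,
    DP   = records$DP < thresholds$dp_min
  )
  failed <- lapply(seq_len(nrow(records)), function(i) {
    hits <- character(0)
    for (f in fields) {
      v <- clause[[f]][i]
      if (is.na(v)) {
        hits <- c(hits, paste0("missing:", f))
      } else if (v) {
        hits <- c(hits, f)
      }
    }
    hits
  })
  records$pass <- lengths(failed) == 0L
  records$failed <- failed
  records
}

#' Count edit classes among passing variant calls
#'
#' Applies the hard filter, keeps SNV records, and counts edits by
#' transition class. Without transcript annotation the strand of an
#' RNA edit is unknowable from the call alone, so A>G and T>C are
#' pooled as the A-to-I class and C>T and G>A as the C-to-U class; the
#' full 12-class transition table is exposed so annotation-aware
#' callers can re-slice. The total passing SNV count (the WGS-style
#' "all SNVs relative to the parent sample" figure) is also returned.
#'
#' @param records A tibble with columns `ref`, `alt`, `QUAL`, `MQ`,
#'   `QD`, `FS`, `DP`.
#' @param thresholds A [filter_thresholds()].
#' @return An `edit_counts` object: list with `transitions` (12-row
#'   tibble of `transition`, `count`), `a_to_i`, `c_to_u`, `n_pass`,
#'   `n_records`, `n_failed_filter`, `n_non_snv`.
#' @export
count_edits <- function(records, thresholds = filter_thresholds()) {
  filtered <- hard_filter(records, thresholds)
  is_snv <- filtered$ref %in% DNA_BASES & filtered$alt %in% DNA_BASES &
    filtered$ref != filtered$alt
  n_non_snv <- sum(!is_snv)
  if (n_non_snv > 0) {
    warn(sprintf("%d non-SNV records skipped", n_non_snv))
  }
  keep <- filtered[is_snv & filtered$pass, , drop = FALSE]
  all_classes <- as.vector(outer(DNA_BASES, DNA_BASES, paste, sep = ">"))
  all_classes <- all_classes[substr(all_classes, 1, 1) !=
                               substr(all_classes, 3, 3)]
  cls <- paste0(keep$ref, ">", keep$alt)
  counts <- vapply(all_classes, function(x) sum(cls == x), integer(1))
  transitions <- tibble(transition = all_classes, count = counts)
  res <- list(
    transitions = transitions,
    a_to_i = counts[["A>G"]] + counts[["T>C"]],
    c_to_u = counts[["C>T"]] + counts[["G>A"]],
    n_pass = nrow(keep),
    n_records = nrow(records),
    n_failed_filter = sum(is_snv & !filtered$pass),
    n_non_snv = n_non_snv
  )
  class(res) <- "edit_counts"
  res
}

#' @exportS3Method base::print
print.edit_counts <- function(x, ...) {
  cat(sprintf("<edit_counts> %d/%d SNVs pass the hard filter\n",
              x$n_pass, x$n_records))
  cat(sprintf("  A-to-I class (A>G + T>C): %d\n", x$a_to_i))
  cat(sprintf("  C-to-U class (C>T + G>A): %d\n", x$c_to_u))
  invisible(x)
}

#' @export
tidy.edit_counts <- function(x, ...) x$transitions

#' @export
glance.edit_counts <- function(x, ...) {
  tibble(n_records = x$n_records, n_pass = x$n_pass,
         n_failed_filter = x$n_failed_filter, n_non_snv = x$n_non_snv,
         a_to_i = x$a_to_i, c_to_u = x$c_to_u)
}

#' Position-level set difference of call sets
#'
#' Drops records whose (contig, pos) also occurs in a parent sample's
#' calls — a helper for comparing edit counts against a parent clone.
#' Whether shared germline variants should be subtracted is the
#' caller's choice; this function only provides the mechanism.
#'
#' @param records,parent Tibbles with `contig` and `pos` columns.
#' @return The subset of `records` at positions absent from `parent`.
#' @export
subtract_parent <- function(records, parent) {
  anti_join(records, parent[, c("contig", "pos")],
            by = c("contig", "pos"))
}
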