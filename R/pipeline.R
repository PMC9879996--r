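# Deterministic end-to-end pipeline over simulated inputs: cohort
# targetability, amplicon quantification and call filtering, written
# as TSV/JSON.  Given the same seed, two runs produce byte-identical
# outputs (the property the determinism tests assert).

#' Run the full simulated pipeline
#'
#' Generates a variant cohort, an edited amplicon read set and a
#' variant-call set from one seed, runs the scanner/classifier, the
#' amplicon quantification and the hard filter over them, and writes
#' all tables (TSV) plus a JSON run summary to `out_dir`. Every source
#' of randomness derives from `seed`, so repeated runs are
#' byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param cohort_size,n_correctable,n_precise Cohort composition.
#' @param read_count Simulated amplicon reads.
#' @param error_rate Per-base sequencing error.
#' @param cohort_editor Editor the cohort construction targets.
#' @param quant_editor Editor used for the amplicon simulation.
#' @param registry Editor registry (default: packaged).
#' @return Invisibly, a named character vector of the files written.
#' @export
run_pipeline <- function(out_dir, seed,
                         cohort_size = 100L, n_correctable = 25L,
                         n_precise = 10L, read_count = 2000L,
                         error_rate = 0.001,
                         cohort_editor = "N-dRRAABE-TadA*(82G)",
                         quant_editor = "N-d12fCBE-3A130",
                         registry = load_registry()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  path <- function(f) file.path(out_dir, f)
  files <- c()

  # --- cohort targetability -------------------------------------------
  cfg <- sim_config(seed, cohort_size = cohort_size,
                    n_correctable = n_correctable, n_precise = n_precise,
                    read_count = read_count, error_rate = error_rate)
  cohort <- simulate_cohort(cfg, registry, cohort_editor)
  fr <- cohort_fractions(cohort$variants, registry,
                         c(cohort_editor, "miniABE-any", "miniCBE-any"))
  readr::write_tsv(cohort$variants[, c("contig", "pos", "ref", "alt",
                                       "label", "flank")],
                   path("cohort_variants.tsv"))
  readr::write_tsv(cohort$truth, path("cohort_truth.tsv"))
  readr::write_tsv(fr, path("cohort_fractions.tsv"))
  files <- c(files, "cohort_variants.tsv", "cohort_truth.tsv",
             "cohort_fractions.tsv")

  # --- amplicon quantification ----------------------------------------
  qspec <- editor(registry, quant_editor)
  amp <- withr::with_seed(seed + 11L, {
    # amplicon with one planted PAM placement; substrate bases at two
    # window positions
    w <- qspec$activity_window
    t1 <- w[1]; t2 <- w[min(2, length(w))]
    chars <- plant_flank(qspec, t1, 40L)
    if (t2 != t1) chars[40L + 1L + (t2 - t1)] <- qspec$edit_from
    paste(chars, collapse = "")
  })
  design <- amplicon_design(amp, qspec, contig = "amp1")
  w <- qspec$activity_window
  planted <- setNames(c(0.25, 0.10)[seq_len(min(2, length(w)))],
                      as.character(w[seq_len(min(2, length(w)))]))
  # keep only positions that actually hold the substrate base
  ref_chars <- strsplit(design$reference, "", fixed = TRUE)[[1]]
  gi <- genomic_index_at(design$placement[rep(1, length(planted)), ],
                         as.integer(names(planted)))
  planted <- planted[strand_base(ref_chars, gi,
                                 design$placement$strand) ==
                       qspec$edit_from]
  outcomes <- c(qspec$edit_to,
                setdiff(DNA_BASES, c(qspec$edit_from, qspec$edit_to)))
  qcfg <- sim_config(seed, read_count = read_count, freqs = planted,
                     purity = setNames(c(0.96, 0.02, 0.02), outcomes),
                     error_rate = error_rate)
  sim <- simulate_reads(design, qcfg)
  m <- tabulate_substitutions(sim$reads, design)
  prof <- window_profile(m)
  win <- call_window(aggregate_profiles(list(prof)))
  pur <- product_purity(m, sim$truth$genomic_pos[1])
  readr::write_tsv(as_tibble(m), path("substitutions.tsv"))
  readr::write_tsv(as_tibble(prof), path("profile.tsv"))
  readr::write_tsv(pur, path("purity.tsv"))
  readr::write_tsv(sim$truth, path("reads_truth.tsv"))
  files <- c(files, "substitutions.tsv", "profile.tsv", "purity.tsv",
             "reads_truth.tsv")

  # --- call filtering --------------------------------------------------
  calls <- simulate_called_variants(cfg)
  filt <- hard_filter(calls$records)
  counts <- count_edits(calls$records)
  flat <- filt
  flat$failed <- vapply(filt$failed, paste, character(1), collapse = ",")
  readr::write_tsv(flat, path("calls_filtered.tsv"))
  readr::write_tsv(tidy(counts), path("edit_classes.tsv"))
  files <- c(files, "calls_filtered.tsv", "edit_classes.tsv")

  # --- run summary ------------------------------------------------------
  summary <- list(
    seed = seed,
    cohort = list(size = cohort_size,
                  editor = cohort_editor,
                  frac_correctable = fr$frac_correctable[fr$editor ==
                    cohort_editor & fr$class == "all"],
                  frac_precise = fr$frac_precise[fr$editor ==
                    cohort_editor & fr$class == "all"]),
    amplicon = list(editor = quant_editor, reads = read_count,
                    window = win$positions, peak = win$peak,
                    purity_defined = attr(pur, "defined")),
    calls = unclass(glance(counts))
  )
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, "summary.json")
  invisible(setNames(file.path(out_dir, files), files))
}
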