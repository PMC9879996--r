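# Seeded synthetic-data generation.
#
# The simulator produces every input the pipeline consumes with known
# ground truth: variant cohorts with planted correctable / precisely
# correctable counts (inverse construction plus rejection against the
# classifier, because uniform background sequence occasionally creates
# incidental PAM placements), amplicon reads with planted per-position
# editing frequencies and purity, and variant-call records planted to
# pass or to fail exactly one filter clause.  A single mandatory seed
# is threaded through all draws; each generator uses a fixed offset
# from it so the same config can feed several generators without
# correlated streams.

#' Simulation configuration
#'
#' All tunable parameters for the synthetic-data generators, with a
#' mandatory seed (no hidden entropy). The defaults describe the
#' emulated study conditions: amplicon sequencing at a few thousand
#' reads per site, an Illumina-like per-base error rate of 1e-3, a
#' 100-variant cohort with 25 correctable sites of which 10 are
#' precisely correctable, and a call set of 60 passing records plus 40
#' single-clause failures.
#'
#' @param seed Integer seed (mandatory).
#' @param read_count Reads per simulated amplicon (default 5000).
#' @param freqs Named numeric vector of planted editing frequencies by
#'   protospacer position, e.g. `c("3" = 0.2, "5" = 0.1)`.
#' @param purity Named numeric vector over outcome bases giving the
#'   product mix among edits (editing-strand bases, must exclude the
#'   substrate base and sum to 1); `NULL` means every edit yields the
#'   canonical product base.
#' @param co_editing `"independent"` (positions edited independently)
#'   or `"linked"` (one latent edited state per read; all planted
#'   frequencies must be equal, and edits are the pure canonical
#'   product so allele-level truth is exact).
#' @param error_rate Per-base sequencing error probability applied
#'   after editing (default 0.001).
#' @param cohort_size,n_correctable,n_precise Cohort composition
#'   (precise is a subset of correctable).
#' @param flank_radius Flank radius for cohort variants (default 30
#'   nt, covering PAM plus 20-nt protospacer in both orientations).
#' @param calls_pass,calls_fail Number of passing call records and a
#'   named integer vector of single-clause failure counts (names among
#'   QUAL, MQ, QD, FS, DP).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       read_count = 5000L,
                       freqs = NULL,
                       purity = NULL,
                       co_editing = c("independent", "linked"),
                       error_rate = 0.001,
                       cohort_size = 100L,
                       n_correctable = 25L,
                       n_precise = 10L,
                       flank_radius = 30L,
                       calls_pass = 60L,
                       calls_fail = c(QUAL = 10L, MQ = 10L, QD = 10L,
                                      FS = 5L, DP = 5L)) {
  if (missing(seed)) {
    abort("seed is mandatory", class = "mbescope_config_error")
  }
  co_editing <- match.arg(co_editing)
  if (error_rate < 0 || error_rate > 1) {
    abort("error_rate must lie in [0, 1]", class = "mbescope_config_error")
  }
  if (!is.null(freqs) && (any(freqs < 0) || any(freqs > 1))) {
    abort("planted frequencies must lie in [0, 1]",
          class = "mbescope_config_error")
  }
  if (!is.null(purity)) {
    if (abs(sum(purity) - 1) > 1e-8 || any(purity < 0)) {
      abort("purity mix must be non-negative and sum to 1",
            class = "mbescope_config_error")
    }
  }
  if (n_precise > n_correctable || n_correctable > cohort_size) {
    abort("need n_precise <= n_correctable <= cohort_size",
          class = "mbescope_config_error")
  }
  structure(list(seed = as.integer(seed), read_count = as.integer(read_count),
                 freqs = freqs, purity = purity, co_editing = co_editing,
                 error_rate = error_rate,
                 cohort_size = as.integer(cohort_size),
                 n_correctable = as.integer(n_correctable),
                 n_precise = as.integer(n_precise),
                 flank_radius = as.integer(flank_radius),
                 calls_pass = as.integer(calls_pass),
                 calls_fail = calls_fail),
            class = "sim_config")
}

#' Random DNA string
#'
#' Uniform composition over A/C/G/T (GC-neutral background). Draws
#' from the current RNG state; seed via the calling generator.
#'
#' @param len Length in nt.
#' @return A DNA string.
#' @export
random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Concrete instantiation of an IUPAC pattern (every ambiguity letter
# resolved to a random unambiguous base it covers).
concrete_pam <- function(pam) {
  pat <- strsplit(pam, "", fixed = TRUE)[[1]]
  vapply(pat, function(p) {
    opts <- intersect(iupac_codes[[p]], DNA_BASES)
    opts[sample.int(length(opts), 1)]
  }, character(1), USE.NAMES = FALSE)
}

# Build one plus-strand flank (character vector) that places the
# centre base at protospacer position t of a planted PAM placement.
# Window positions other than t are cleared of substrate bases; the
# positions in `bystander_at` are then set to the substrate base.
plant_flank <- function(spec, t, radius, bystander_at = integer(0)) {
  width <- 2L * radius + 1L
  center <- radius + 1L
  chars <- sample(DNA_BASES, width, replace = TRUE)
  m <- nchar(spec$pam)
  L <- spec$protospacer_length
  if (spec$convention == "cas12f_r_zero") {
    anchor <- center - t
    pam_start <- anchor - m + 1L
    proto_start <- anchor + 1L
  } else {
    proto_start <- center - t + 1L
    pam_start <- proto_start + L
  }
  chars[pam_start:(pam_start + m - 1L)] <- concrete_pam(spec$pam)
  pos_to_g <- function(q) {
    if (spec$convention == "cas12f_r_zero") center - t + q else {
      proto_start + q - 1L
    }
  }
  not_sub <- setdiff(DNA_BASES, spec$edit_from)
  for (q in setdiff(spec$activity_window, t)) {
    g <- pos_to_g(q)
    chars[g] <- sample(not_sub, 1)
  }
  for (q in bystander_at) chars[pos_to_g(q)] <- spec$edit_from
  chars[center] <- spec$edit_from # alt allele during construction
  chars
}

#' Simulate a variant cohort with planted targetability
#'
#' Emits `cohort_size` SNVs whose flanks are constructed so that
#' exactly `n_correctable` are correctable and exactly `n_precise` of
#' those are precisely correctable by the named editor. Construction
#' is inverse (choose a target position in or out of the window, plant
#' or withhold the PAM, plant or withhold bystanders) followed by
#' verification with the package classifier and rejection resampling,
#' since uniform background sequence occasionally creates incidental
#' placements that would otherwise flip a verdict. Non-correctable
#' variants are an even mix of chemistry-incompatible transversions
#' and right-chemistry variants with no qualifying placement.
#'
#' @param cfg A [sim_config()].
#' @param registry An `editor_registry`.
#' @param editor_name Editor the planted counts refer to.
#' @return A list with `variants` (a [variant_table()] tibble, one
#'   contig per variant with the variant at the flank centre) and
#'   `truth` (tibble of `contig`, `planted` category, `correctable`,
#'   `precise`).
#' @export
simulate_cohort <- function(cfg, registry, editor_name) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- editor(registry, editor_name)
  win <- spec$activity_window
  prec <- spec$precision_window
  n_corr_only <- cfg$n_correctable - cfg$n_precise
  if (n_corr_only > 0 && length(win) < 2 && setequal(win, prec)) {
    abort(paste0("cannot plant correctable-but-imprecise variants for an ",
                 "editor whose activity window is a single precise position"),
          class = "mbescope_config_error")
  }
  radius <- cfg$flank_radius
  center <- radius + 1L

  withr::with_seed(cfg$seed + 101L, {
    cats <- c(rep("precise", cfg$n_precise),
              rep("correctable", n_corr_only),
              rep("background", cfg$cohort_size - cfg$n_correctable))
    cats <- sample(cats)

    build_one <- function(category) {
      for (attempt in 1:300) {
        mirror <- runif(1) < 0.5
        if (category == "precise") {
          t <- prec[sample.int(length(prec), 1)]
          chars <- plant_flank(spec, t, radius)
          ref <- spec$edit_to; alt <- spec$edit_from
        } else if (category == "correctable") {
          if (length(win) >= 2) {
            t <- win[sample.int(length(win), 1)]
            q <- setdiff(win, t)
            bys <- q[sample.int(length(q), 1)]
            chars <- plant_flank(spec, t, radius, bystander_at = bys)
          } else {
            t <- setdiff(win, prec)[1]
            chars <- plant_flank(spec, t, radius)
          }
          ref <- spec$edit_to; alt <- spec$edit_from
        } else {
          chars <- sample(DNA_BASES, 2L * radius + 1L, replace = TRUE)
          if (runif(1) < 0.5) {
            # chemistry-incompatible change: never correctable
            correctable_pairs <- rbind(
              c(spec$edit_to, spec$edit_from),
              dna_complement(c(spec$edit_to, spec$edit_from)))
            repeat {
              pair <- sample(DNA_BASES, 2)
              if (!any(correctable_pairs[, 1] == pair[1] &
                         correctable_pairs[, 2] == pair[2])) break
            }
            ref <- pair[1]; alt <- pair[2]
          } else {
            # right chemistry, but no qualifying placement
            ref <- spec$edit_to; alt <- spec$edit_from
          }
        }
        flank <- paste(chars, collapse = "")
        flank <- set_base(flank, center, ref)
        if (mirror) {
          flank <- dna_revcomp(flank)
          ref <- dna_complement(ref); alt <- dna_complement(alt)
        }
        v <- variant_table("tmp", center, ref, alt, flank,
                           label = "Pathogenic")
        cl <- classify_precise(v, spec)
        ok <- switch(category,
                     precise = cl$correctable && cl$precise,
                     correctable = cl$correctable && !cl$precise,
                     background = !cl$correctable)
        if (ok) {
          return(list(ref = ref, alt = alt, flank = flank,
                      correctable = cl$correctable, precise = cl$precise))
        }
      }
      abort(sprintf("could not construct a '%s' variant in 300 attempts",
                    category), class = "mbescope_config_error")
    }

    built <- lapply(cats, build_one)
    contigs <- sprintf("var%04d", seq_along(built))
    variants <- variant_table(
      contig = contigs, pos = center,
      ref = vapply(built, `[[`, character(1), "ref"),
      alt = vapply(built, `[[`, character(1), "alt"),
      flank = vapply(built, `[[`, character(1), "flank"),
      label = "Pathogenic"
    )
    truth <- tibble(contig = contigs, planted = cats,
                    correctable = vapply(built, `[[`, logical(1),
                                         "correctable"),
                    precise = vapply(built, `[[`, logical(1), "precise"))
    list(variants = variants, truth = truth)
  })
}

#' Simulate amplicon reads with planted editing
#'
#' Draws `read_count` gapless copies of the design's reference, edits
#' them at the planted protospacer positions under the chosen
#' co-editing model, then applies uniform per-base sequencing error.
#' Under the independent model each position converts independently
#' with its planted frequency and the outcome base is drawn from the
#' purity mix; under the linked model a single latent edited state per
#' read converts every planted position to the canonical product base
#' (all planted frequencies must be equal).
#'
#' @param design An [amplicon_design()].
#' @param cfg A [sim_config()] whose `freqs` element names protospacer
#'   positions; every named position must hold the substrate base on
#'   the editing strand, else a config error is raised.
#' @return A list with `reads` (character vector), `truth` (tibble of
#'   `position`, `genomic_pos`, `planted_freq`, `n_edited`,
#'   `realized_freq`, counting pre-error edits), and `n_edited_reads`
#'   (linked model: reads in the edited latent state).
#' @export
simulate_reads <- function(design, cfg) {
  stopifnot(inherits(design, "amplicon_design"),
            inherits(cfg, "sim_config"))
  spec <- design$spec
  pl <- design$placement
  freqs <- cfg$freqs
  if (is.null(freqs) || length(freqs) == 0) {
    abort("cfg$freqs must name at least one protospacer position",
          class = "mbescope_config_error")
  }
  posn <- as.integer(names(freqs))
  gi <- genomic_index_at(pl[rep(1, length(posn)), , drop = FALSE], posn)
  ref_chars <- strsplit(design$reference, "", fixed = TRUE)[[1]]
  bad <- is.na(gi) | strand_base(ref_chars, gi, pl$strand) != spec$edit_from
  if (any(bad)) {
    abort(sprintf("planted positions without a %s on the editing strand: %s",
                  spec$edit_from, paste(posn[bad], collapse = ", ")),
          class = "mbescope_config_error")
  }
  purity <- cfg$purity %||% setNames(1, spec$edit_to)
  if (spec$edit_from %in% names(purity)) {
    abort("purity mix may not include the substrate base",
          class = "mbescope_config_error")
  }
  if (cfg$co_editing == "linked" && length(unique(freqs)) > 1) {
    abort("linked co-editing requires one shared planted frequency",
          class = "mbescope_config_error")
  }

  n <- cfg$read_count
  len <- length(ref_chars)
  withr::with_seed(cfg$seed + 202L, {
    m <- matrix(rep(ref_chars, each = n), nrow = n, ncol = len)
    n_edited <- integer(length(posn))
    n_edited_reads <- NA_integer_
    to_plus <- function(b) if (pl$strand == "+") b else dna_complement(b)
    if (cfg$co_editing == "independent") {
      for (k in seq_along(posn)) {
        hit <- runif(n) < freqs[k]
        n_edited[k] <- sum(hit)
        if (n_edited[k] > 0) {
          outc <- sample(names(purity), n_edited[k], replace = TRUE,
                         prob = purity)
          m[hit, gi[k]] <- to_plus(outc)
        }
      }
    } else {
      edited <- runif(n) < freqs[[1]]
      n_edited_reads <- sum(edited)
      for (k in seq_along(posn)) {
        m[edited, gi[k]] <- to_plus(spec$edit_to)
        n_edited[k] <- n_edited_reads
      }
    }
    if (cfg$error_rate > 0) {
      idx <- which(runif(n * len) < cfg$error_rate)
      if (length(idx) > 0) {
        cur <- m[idx]
        # replace with one of the three other bases, uniformly
        alt3 <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                      G = c("A", "C", "T"), T = c("A", "C", "G"))
        pick <- sample.int(3, length(idx), replace = TRUE)
        m[idx] <- alt3[cbind(match(cur, rownames(alt3)), pick)]
      }
    }
    reads <- apply(m, 1, paste, collapse = "")
    truth <- tibble(position = posn, genomic_pos = gi,
                    planted_freq = unname(freqs),
                    n_edited = n_edited,
                    realized_freq = n_edited / n)
    list(reads = reads, truth = truth, n_edited_reads = n_edited_reads)
  })
}

#' Simulate variant-call records with planted filter outcomes
#'
#' Emits `calls_pass` records whose QUAL/MQ/QD/FS/DP all pass the hard
#' filter, plus, for each named clause in `calls_fail`, records
#' constructed to fail exactly that one clause. Transition classes are
#' drawn uniformly over the 12 SNV classes. Rows are shuffled; the
#' truth table records each record's planted verdict and clause.
#'
#' @param cfg A [sim_config()].
#' @param thresholds A [filter_thresholds()].
#' @return A list with `records` (tibble of `contig`, `pos`, `ref`,
#'   `alt`, `QUAL`, `MQ`, `QD`, `FS`, `DP`) and `truth` (tibble of
#'   `pos`, `planted_pass`, `planted_clause`).
#' @export
simulate_called_variants <- function(cfg, thresholds = filter_thresholds()) {
  stopifnot(inherits(cfg, "sim_config"))
  fail <- cfg$calls_fail
  if (length(fail) > 0 &&
      !all(names(fail) %in% c("QUAL", "MQ", "QD", "FS", "DP"))) {
    abort("calls_fail names must be among QUAL, MQ, QD, FS, DP",
          class = "mbescope_config_error")
  }
  n <- cfg$calls_pass + sum(fail)
  withr::with_seed(cfg$seed + 303L, {
    passing <- function(k) {
      tibble(QUAL = runif(k, thresholds$qual_min, thresholds$qual_min + 40),
             MQ = runif(k, thresholds$mq_min, thresholds$mq_min + 40),
             QD = runif(k, thresholds$qd_min, thresholds$qd_min + 28),
             FS = runif(k, 0, thresholds$fs_max),
             DP = sample(thresholds$dp_min:(thresholds$dp_min + 80), k,
                         replace = TRUE))
    }
    recs <- passing(n)
    clause <- rep("none", n)
    i <- cfg$calls_pass
    for (f in names(fail)) {
      k <- fail[[f]]
      if (k == 0) next
      rows <- (i + 1):(i + k)
      recs[[f]][rows] <- switch(
        f,
        QUAL = runif(k, 0, thresholds$qual_min - 0.1),
        MQ = runif(k, 0, thresholds$mq_min - 0.1),
        QD = runif(k, 0, thresholds$qd_min - 0.1),
        FS = runif(k, thresholds$fs_max + 0.1, thresholds$fs_max + 30),
        DP = sample(0:(thresholds$dp_min - 1), k, replace = TRUE)
      )
      clause[rows] <- f
      i <- i + k
    }
    pair <- t(replicate(n, sample(DNA_BASES, 2)))
    ord <- sample.int(n)
    records <- tibble(contig = "rna1", pos = sort(sample.int(10 * n, n)),
                      ref = pair[, 1], alt = pair[, 2])
    records <- dplyr::bind_cols(records, recs)[ord, ]
    truth <- tibble(pos = records$pos,
                    planted_pass = clause[ord] == "none",
                    planted_clause = clause[ord])
    list(records = records, truth = truth)
  })
}
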