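# Small hand-built read sets with known counts.

make_design <- function(spec = toy_cbe(window = 3:6), substrate_at = c(3, 5)) {
  withr::with_seed(101, planted_design(
    planted_amplicon(spec, substrate_at), spec, substrate_at))
}

edit_read <- function(ref, at, base) {
  for (i in seq_along(at)) substr(ref, at[i], at[i]) <- base[i]
  ref
}

test_that("substitution tallies count calls and exclude N from depth", {
  d <- make_design()
  g3 <- genomic_index_at(d$placement, 3L)
  reads <- c(rep(edit_read(d$reference, g3, "T"), 3),
             rep(d$reference, 7))
  m <- tabulate_substitutions(reads, d)
  expect_identical(m$T[g3], 3L)
  expect_identical(m$depth[g3], 10L)
  expect_identical(m$T[g3] / m$depth[g3], 0.3)
  # an N call drops out of the denominator at that position only
  reads_n <- c(reads[1:9], edit_read(d$reference, g3, "N"))
  mn <- tabulate_substitutions(reads_n, d)
  expect_identical(mn$depth[g3], 9L)
  expect_identical(mn$depth[g3 + 1L], 10L)
  # all-reference reads give zero off-reference frequency everywhere
  m0 <- tabulate_substitutions(rep(d$reference, 5), d)
  off <- vapply(seq_len(nrow(m0)), function(i) {
    sum(m0[i, setdiff(c("A", "C", "G", "T"), m0$ref[i])])
  }, numeric(1))
  expect_true(all(off == 0))
})

test_that("length-mismatched reads are rejected, with a hard error past 50%", {
  d <- make_design()
  short <- substr(d$reference, 1, 10)
  expect_warning(m <- tabulate_substitutions(c(rep(d$reference, 3), short), d),
                 regexp = "rejected")
  expect_identical(attr(m, "n_rejected"), 1L)
  expect_error(
    suppressWarnings(tabulate_substitutions(c(d$reference, short, short), d)),
    class = "mbescope_input_error")
})

test_that("window profiles map frequencies onto protospacer positions", {
  d <- make_design()
  g3 <- genomic_index_at(d$placement, 3L)
  reads <- c(rep(edit_read(d$reference, g3, "T"), 2), rep(d$reference, 8))
  p <- window_profile(tabulate_substitutions(reads, d))
  expect_identical(p$frequency[p$position == 3], 0.2)
  expect_identical(p$frequency[p$position == 5], 0)
  # positions without the substrate base are absent, not zero
  expect_false(4 %in% p$position)
})

test_that("minus-strand designs report complement-corrected frequencies", {
  spec <- toy_cbe(window = 3:6)
  withr::with_seed(103, {
    ref_plus <- planted_amplicon(spec, c(3, 5))
  })
  d_plus <- planted_design(ref_plus, spec, c(3, 5))
  g3 <- genomic_index_at(d_plus$placement, 3L)
  reads_plus <- c(rep(edit_read(ref_plus, g3, "T"), 3), rep(ref_plus, 7))
  # same molecules sequenced in the opposite orientation
  ref_minus <- dna_revcomp(ref_plus)
  reads_minus <- dna_revcomp(reads_plus)
  pl <- find_pam_sites(ref_minus, spec)
  pos <- protospacer_position(pl, nchar(ref_minus) - g3 + 1L)
  row <- which(pl$strand == "-" & !is.na(pos) & pos == 3L)[1]
  d_minus <- amplicon_design(ref_minus, spec,
                             placement = pl[row, , drop = FALSE])
  p_plus <- window_profile(tabulate_substitutions(reads_plus, d_plus))
  p_minus <- window_profile(tabulate_substitutions(reads_minus, d_minus))
  expect_identical(p_plus$position, p_minus$position)
  expect_identical(p_plus$frequency, p_minus$frequency)
  expect_identical(p_plus$context3, p_minus$context3)
})

test_that("aggregation averages present positions only and is identity for one profile", {
  a <- tibble::tibble(position = c(2L, 4L), frequency = c(0.05, 0.10),
                      site = 1L)
  b <- tibble::tibble(position = 4L, frequency = 0.30, site = 2L)
  cc <- tibble::tibble(position = 4L, frequency = 0.20, site = 3L)
  agg <- aggregate_profiles(dplyr::bind_rows(a, b, cc))
  expect_identical(agg$mean[agg$position == 4], 0.2)
  expect_identical(agg$n[agg$position == 4], 3L)
  expect_identical(agg$n[agg$position == 2], 1L) # absent elsewhere
  one <- aggregate_profiles(a)
  expect_identical(one$mean, a$frequency)
  expect_identical(one$n, c(1L, 1L))
})

test_that("window calling applies the half-maximum rule with smallest-position ties", {
  agg <- tibble::tibble(position = c(2L, 3L, 4L, 6L),
                        mean = c(0.10, 0.11, 0.095, 0.02))
  w <- call_window(agg)
  expect_identical(w$positions, c(2L, 3L, 4L))
  expect_identical(w$peak, 3L)
  single <- call_window(tibble::tibble(position = c(3L, 7L),
                                       mean = c(0.2, 0)))
  expect_identical(single$positions, 3L)
  uniform <- call_window(tibble::tibble(position = c(5L, 2L, 9L),
                                        mean = 0.1))
  expect_identical(uniform$positions, c(2L, 5L, 9L))
  expect_identical(uniform$peak, 2L)
  zero <- call_window(tibble::tibble(position = 1:3, mean = 0))
  expect_identical(zero$positions, integer(0))
  expect_true(is.na(zero$peak))
})

test_that("product purity partitions edited reads and guards division by zero", {
  d <- make_design()
  g3 <- genomic_index_at(d$placement, 3L)
  reads <- c(rep(edit_read(d$reference, g3, "T"), 7),
             rep(edit_read(d$reference, g3, "G"), 2),
             rep(edit_read(d$reference, g3, "A"), 1),
             rep(d$reference, 10))
  pur <- product_purity(tabulate_substitutions(reads, d), g3)
  expect_identical(pur$fraction[pur$outcome == "C>T"], 0.7)
  expect_identical(sum(pur$fraction), 1)
  expect_identical(attr(pur, "n_edited"), 10L)
  # all edits to T
  pur1 <- product_purity(tabulate_substitutions(
    rep(edit_read(d$reference, g3, "T"), 4), d), g3)
  expect_identical(pur1$fraction[pur1$outcome == "C>T"], 1)
  # zero edited reads: undefined and flagged
  pur0 <- product_purity(tabulate_substitutions(rep(d$reference, 4), d), g3)
  expect_false(attr(pur0, "defined"))
  expect_true(all(is.na(pur0$fraction)))
  # querying a non-substrate position is a usage error
  g4 <- genomic_index_at(d$placement, 4L)
  expect_error(product_purity(tabulate_substitutions(reads, d), g4),
               class = "mbescope_usage_error")
})

test_that("allele tables report desired proportions among all and edited reads", {
  d <- make_design() # substrate at positions 3 and 5
  g3 <- genomic_index_at(d$placement, 3L)
  g5 <- genomic_index_at(d$placement, 5L)
  reads <- c(rep(edit_read(d$reference, g3, "T"), 40),
             rep(edit_read(d$reference, c(g3, g5), c("T", "T")), 10),
             rep(d$reference, 50))
  ao <- allele_outcomes(reads, d, desired = c("3" = "T"))
  expect_identical(ao$desired_among_edited, 0.8)
  expect_identical(ao$desired_among_all, 0.4)
  expect_identical(sum(ao$table$proportion), 1)
  expect_identical(sum(ao$table$is_reference), 1L)
  # reads with N at a window position are excluded and counted
  reads_n <- c(reads, edit_read(d$reference, g3, "N"))
  ao_n <- allele_outcomes(reads_n, d, desired = c("3" = "T"))
  expect_identical(ao_n$n_excluded, 1L)
  expect_identical(ao_n$n_reads, 100L)
  # all unedited: desired proportion among all is 0
  ao0 <- allele_outcomes(rep(d$reference, 5), d, desired = c("3" = "T"))
  expect_identical(ao0$desired_among_all, 0)
  expect_true(is.na(ao0$desired_among_edited))
})

test_that("context preference recovers a planted ranking and reports exact ties", {
  spec <- toy_cbe(window = 3:10)
  withr::with_seed(107, {
    # amplicon holding CA, CT, CC, CG contexts at substrate positions
    amp <- planted_amplicon(spec, c(3, 5, 7, 9))
    chars <- strsplit(amp, "", fixed = TRUE)[[1]]
    g <- vapply(c(3, 5, 7, 9), function(q) 41L - 3L + as.integer(q), 0L)
    chars[g + 1L] <- c("A", "T", "C", "G")
    amp <- paste(chars, collapse = "")
    d <- planted_design(amp, spec, 3)
    # plant: CA edited at 0.6, the rest at 0.2
    ref <- d$reference
    n <- 1000L
    reads <- vapply(seq_len(n), function(i) {
      r <- ref
      if (runif(1) < 0.6) r <- edit_read(r, g[1], "T")
      for (k in 2:4) if (runif(1) < 0.2) r <- edit_read(r, g[k], "T")
      r
    }, character(1))
    p <- window_profile(tabulate_substitutions(reads, d))
    pref <- context_preference(p, side = "three_prime")
    ca <- pref[pref$context == "CA", ]
    expect_identical(ca$rank, 1L)
    expect_true(abs(ca$mean_freq - 0.6) < 3 * sqrt(0.6 * 0.4 / n))
  })
  # exact ties share a rank
  prof <- tibble::tibble(position = 1:2, frequency = c(0.2, 0.2),
                         context3 = c("CA", "CT"), context5 = c("AC", "TC"))
  tied <- context_preference(prof)
  expect_identical(tied$rank, c(1L, 1L))
})

test_that("on/off ratios floor zero off-target editing at one read", {
  r <- on_off_ratio(0.20, 0.005, 1000)
  expect_identical(r$ratio, 40)
  expect_false(r$floored)
  r0 <- on_off_ratio(0.20, 0, 1000)
  expect_identical(r0$ratio, 200)
  expect_true(r0$floored)
  expect_identical(on_off_ratio(0, 0.01, 500)$ratio, 0)
  expect_error(on_off_ratio(0.2, 0.1, 0), class = "mbescope_usage_error")
})

test_that("R-loop statistics sum and maximise per-base frequencies with tie rules", {
  d <- make_design(toy_cbe(window = 3:6), substrate_at = c(3, 4, 5))
  g <- genomic_index_at(d$placement[rep(1, 3), ], c(3L, 4L, 5L))
  reads <- c(edit_read(d$reference, g[1], "T"), # 1/100 at g3
             rep(edit_read(d$reference, g[2], "T"), 2), # 2/100
             rep(edit_read(d$reference, g[3], "T"), 3), # 3/100
             rep(d$reference, 94))
  m <- tabulate_substitutions(reads, d)
  rs <- rloop_stats(m, c(min(g), max(g)), base = "C")
  expect_equal(rs$sum_freq, 0.06)
  expect_equal(rs$max_freq, 0.03)
  expect_identical(rs$max_pos, g[3])
  # window with no cytosine: zero sum, undefined max
  no_c <- which(m$ref != "C")
  rs0 <- rloop_stats(m, c(no_c[1], no_c[1]), base = "C")
  expect_identical(rs0$sum_freq, 0)
  expect_false(rs0$defined)
  # tie on the maximum resolves to the smaller coordinate
  reads_tie <- c(rep(edit_read(d$reference, g[1], "T"), 2),
                 rep(edit_read(d$reference, g[2], "T"), 2),
                 rep(d$reference, 96))
  rst <- rloop_stats(tabulate_substitutions(reads_tie, d),
                     c(min(g), max(g)), base = "C")
  expect_identical(rst$max_pos, g[1])
})

test_that("frequencies and allele proportions conserve mass under simulation", {
  spec <- toy_cbe(window = 3:6)
  withr::with_seed(109, {
    amp <- planted_amplicon(spec, c(3, 5))
  })
  d <- planted_design(amp, spec, c(3, 5))
  cfg <- sim_config(23, read_count = 400, freqs = c("3" = 0.4, "5" = 0.2),
                    purity = c(T = 0.9, G = 0.06, A = 0.04),
                    error_rate = 0.002)
  sim <- simulate_reads(d, cfg)
  m <- tabulate_substitutions(sim$reads, d)
  g3 <- sim$truth$genomic_pos[1]
  pur <- product_purity(m, g3)
  expect_equal(sum(pur$fraction), 1)
  ao <- allele_outcomes(sim$reads, d, desired = c("3" = "T"))
  expect_equal(sum(ao$table$proportion), 1)
})
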