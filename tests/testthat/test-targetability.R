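# Toy flanks are built around a 61-nt window with the variant at
# position 31 (30-nt radius).

flank_with <- function(edits, base = NULL) {
  # edits: named list position -> base, applied to a fixed background
  chars <- strsplit(base %||% strrep("G", 61), "", fixed = TRUE)[[1]]
  for (at in names(edits)) chars[as.integer(at)] <- edits[[at]]
  paste(chars, collapse = "")
}

test_that("a G>A variant 3 nt downstream of a plus-strand TTTA is correctable", {
  spec <- toy_abe(window = 3:4)
  # anchor (R) at 28 so the centre sits at protospacer position 3
  fl <- flank_with(list(`25` = "T", `26` = "T", `27` = "T", `28` = "A",
                        `31` = "G", `32` = "C"))
  v <- variant_table("c", 31, "G", "A", fl)
  res <- classify_precise(v, spec)
  expect_true(res$correctable)
  expect_true(res$precise) # position 4 holds C: no bystander
  expect_identical(res$placements[[1]]$position, 3L)
  # with an A bystander at position 4, still correctable but imprecise
  fl2 <- flank_with(list(`25` = "T", `26` = "T", `27` = "T", `28` = "A",
                         `31` = "G", `32` = "A"))
  res2 <- classify_precise(variant_table("c", 31, "G", "A", fl2), spec)
  expect_true(res2$correctable)
  expect_false(res2$precise)
  expect_identical(res2$placements[[1]]$bystanders[[1]], 4L)
})

test_that("transversions are never correctable by either chemistry", {
  fl <- flank_with(list(`31` = "A"))
  v <- variant_table("c", 31, "A", "T", fl)
  expect_false(classify_correctable(v, toy_abe())$correctable)
  expect_false(classify_correctable(v, toy_cbe())$correctable)
})

test_that("an A>G variant is correctable via a minus-strand CBE placement", {
  spec <- toy_cbe(window = 3L)
  # minus-strand TTTG: plus footprint CAAA at 34..37; its R sits at 34,
  # putting the centre (31) at protospacer position 3 on the minus strand
  fl <- flank_with(list(`34` = "C", `35` = "A", `36` = "A", `37` = "A",
                        `31` = "A"), base = strrep("G", 61))
  v <- variant_table("c", 31, "A", "G", fl)
  res <- classify_correctable(v, spec)
  expect_true(res$correctable)
  expect_identical(res$placements[[1]]$strand, "-")
  expect_identical(res$placements[[1]]$position, 3L)
})

test_that("precision requires the precision window and excludes bystander placements", {
  spec <- toy_abe(window = c(3L, 4L, 5L), precision = 3L)
  # centre reachable only at position 5 (anchor at 26): outside precision
  fl <- flank_with(list(`23` = "T", `24` = "T", `25` = "T", `26` = "A",
                        `31` = "G", `29` = "C", `30` = "C"))
  res <- classify_precise(variant_table("c", 31, "G", "A", fl), spec)
  expect_true(res$correctable)
  expect_false(res$precise)
  # relaxed scope: bystanders outside the precision window are tolerated
  spec2 <- toy_abe(window = 3:4, precision = 3L)
  fl2 <- flank_with(list(`25` = "T", `26` = "T", `27` = "T", `28` = "A",
                         `31` = "G", `32` = "A"))
  v2 <- variant_table("c", 31, "G", "A", fl2)
  expect_false(classify_precise(v2, spec2)$precise)
  expect_true(classify_precise(v2, spec2,
                               bystander_scope = "precision_window")$precise)
})

test_that("a flank too short to scan raises an undeterminable error, not FALSE", {
  spec <- toy_abe()
  fl <- paste0(strrep("G", 10), "G", strrep("G", 10))
  v <- variant_table("c", 11, "G", "A", fl)
  expect_error(classify_correctable(v, spec),
               class = "mbescope_undeterminable_error")
  # unless the chemistry already rules the variant out
  v2 <- variant_table("c", 11, "G", "C", paste0(strrep("G", 10), "G",
                                                strrep("G", 10)))
  expect_false(classify_correctable(v2, spec)$correctable)
})

test_that("classifier verdicts agree with the brute-force oracle", {
  specs <- list(toy_abe(), toy_cbe(window = c(3L, 5L, 8L), precision = 3L))
  withr::with_seed(7, {
    for (i in 1:60) {
      spec <- specs[[1 + i %% 2]]
      rv <- random_variant(spec)
      if (rv$ref == rv$alt) next
      v <- variant_table("c", 31, rv$ref, rv$alt, rv$flank)
      got <- classify_precise(v, spec)
      want <- oracle_classify(rv$flank, rv$ref, rv$alt, spec)
      expect_identical(got$correctable, want$correctable)
      expect_identical(got$precise, want$precise)
    }
  })
})

test_that("verdicts are invariant under reverse-complementing the flank", {
  spec <- toy_abe()
  withr::with_seed(11, {
    for (i in 1:40) {
      rv <- random_variant(spec)
      v <- variant_table("c", 31, rv$ref, rv$alt, rv$flank)
      w <- variant_table("c", 31, dna_complement(rv$ref),
                         dna_complement(rv$alt), dna_revcomp(rv$flank))
      a <- classify_precise(v, spec)
      b <- classify_precise(w, spec)
      expect_identical(a$correctable, b$correctable)
      expect_identical(a$precise, b$precise)
    }
  })
})

test_that("precise implies correctable on random inputs", {
  spec <- toy_cbe(window = 3:6, precision = 3:4)
  withr::with_seed(13, {
    for (i in 1:60) {
      rv <- random_variant(spec)
      res <- classify_precise(variant_table("c", 31, rv$ref, rv$alt,
                                            rv$flank), spec)
      expect_true(!res$precise || res$correctable)
    }
  })
})

test_that("installation design enumerates, ranks and refuses correctly", {
  spec <- toy_cbe(window = 3:8, precision = 3:4,
                  preferred_positions = 3:5)
  # one placement putting the single C at position 3, no other C in window
  s <- flank_with(list(`25` = "T", `26` = "T", `27` = "T", `28` = "A",
                       `31` = "C"))
  out <- design_installation(s, 31, "C", "T", spec)
  expect_identical(nrow(out), 1L)
  expect_true(out$in_precision[1])
  expect_identical(out$n_bystanders[1], 0L)
  # no PAM anywhere: empty candidate list
  out2 <- design_installation(flank_with(list(`31` = "C")), 31, "C", "T",
                              spec)
  expect_identical(nrow(out2), 0L)
  # chemistry-incompatible request errors, naming both strands
  expect_error(design_installation(s, 31, "C", "G", spec),
               regexp = "C>T.*G>A", class = "mbescope_usage_error")
  # two placements: anchor 28 puts the target at position 3 with no
  # bystander; anchor 23 puts it at position 8 with a bystander C at
  # its position 6.  The clean, precise placement must rank first.
  s3 <- flank_with(list(`20` = "T", `21` = "T", `22` = "T", `23` = "A",
                        `25` = "T", `26` = "T", `27` = "T", `28` = "A",
                        `29` = "C", `31` = "C"))
  out3 <- design_installation(s3, 31, "C", "T", spec)
  expect_identical(nrow(out3), 2L)
  expect_identical(out3$position[1], 3L)
  expect_identical(out3$n_bystanders, c(0L, 1L))
  expect_true(out3$in_precision[1])
})

test_that("cohort fractions recover planted, unit and zero fractions", {
  spec_name <- "N-dRRAABE-TadA*(82G)"
  reg <- load_registry()
  # single correctable variant -> fraction 1.0 in its class
  fl <- flank_with(list(`25` = "T", `26` = "T", `27` = "T", `28` = "A",
                        `31` = "G", `32` = "C"))
  v <- variant_table("c", 31, "G", "A", fl)
  fr <- cohort_fractions(v, reg, spec_name)
  expect_identical(fr$frac_correctable[fr$class == "G>A"], 1)
  expect_identical(fr$frac_correctable[fr$class == "all"], 1)
  # empty classes are undefined, not zero
  expect_true(is.na(fr$frac_correctable[fr$class == "A>G"]))
  # a PAM-free cohort scores zero everywhere defined
  v0 <- variant_table(c("a", "b"), 31, c("G", "C"), c("A", "T"),
                      c(flank_with(list(`31` = "G")),
                        flank_with(list(`31` = "C"))))
  fr0 <- cohort_fractions(v0, reg, c(spec_name, "miniCBE-any"))
  expect_true(all(fr0$frac_correctable[!is.na(fr0$frac_correctable)] == 0))
  expect_error(cohort_fractions(v[0, ], reg, spec_name),
               class = "mbescope_usage_error")
})
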