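# mbescope

Targeting scope and outcome quantification for miniature CRISPR base
editors.

Hypercompact Cas12f-derived base editors (miniABEs and miniCBEs) are
small enough for single-AAV delivery, which makes them attractive
therapeutic tools — but their strict TTTR PAM and narrow, construct-
specific editing windows mean that whether a given pathogenic SNV is
reachable at all, and whether it can be reverted *without bystander
edits*, is a non-trivial geometric question. `mbescope` is an R package
for scientists engineering or applying such editors. It provides:

* **A curated editor registry** (`load_registry()`): each editor as
  data — chemistry (A→G or C→T), PAM pattern and side, coordinate
  convention, activity / precision windows as explicit position sets,
  preferred positions and dinucleotide context preference — with a
  mandatory provenance note per entry. Both Cas12f (`TTTR` 5′ of the
  protospacer, the R counted as position 0) and SpCas9-style (`NGG` 3′,
  positions 1–20 from the PAM-distal end) conventions are first-class.
* **PAM scanning and coordinate algebra** (`find_pam_sites()`,
  `protospacer_position()`, `genomic_index_at()`): every oriented
  placement on both strands, with exact conversion between genomic
  indices and protospacer positions.
* **Variant targetability** (`classify_correctable()`,
  `classify_precise()`, `design_installation()`,
  `cohort_fractions()`): a variant is *correctable* by an editor iff
  the alt allele, read on either strand, is the editor's substrate
  base at an activity-window position of some placement on the
  alt-carrying flank such that editing restores the reference; it is
  *precisely* correctable iff some such placement puts the target in
  the precision window with zero same-chemistry bystanders in the
  window. Installation design enumerates and ranks sgRNA placements by
  (precision, bystander count, preferred position, position).
* **Amplicon quantification** (`tabulate_substitutions()`,
  `window_profile()`, `aggregate_profiles()`, `call_window()`,
  `product_purity()`, `allele_outcomes()`, `context_preference()`,
  `on_off_ratio()`, `rloop_stats()`): per-position substitution
  matrices from gapless amplicon reads and every editing statistic
  derived from them — editing-window profiles, product purity, allele
  homogeneity, sequence-context preference, on/off-target ratios and
  R-loop sum/max statistics.
* **Variant-call hard filtering** (`hard_filter()`, `count_edits()`):
  the five-clause disjunction `QUAL < 25 || MQ < 20.0 || QD < 2.0 ||
  FS > 30.0 || DP < 20` (boundary values pass), with A-to-I (A>G +
  T>C) and C-to-U (C>T + G>A) RNA-edit class counting and a full
  12-class transition table.
* **A seeded simulator** (`sim_config()`, `simulate_cohort()`,
  `simulate_reads()`, `simulate_called_variants()`) generating every
  input with known ground truth — planted targetable fractions,
  planted per-position editing frequencies and purity mixes, planted
  filter outcomes — so the whole pipeline is testable end to end.

All user-facing functions take and return tibbles, chain with the
pipe, and have `ggplot2::autoplot()` / `tidy()` / `glance()` methods
where a result type warrants one.

## Worked example

Is a pathogenic G>A variant reachable by the precise miniABE
`N-dRRAABE-TadA*(82G)` (activity window A3–A4)? The flank below
carries a TTTA PAM whose R sits 3 nt upstream of the variant:

```r
library(mbescope)
reg <- load_registry()
abe <- reg[["N-dRRAABE-TadA*(82G)"]]

flank <- paste0(strrep("G", 24), "TTTA", "GGGCGG", strrep("G", 27))
v <- variant_table("chr5", 31, "G", "A", flank, label = "Pathogenic")
res <- classify_precise(v, abe)
res[, c("contig", "pos", "ref", "alt", "editor", "correctable", "precise")]
#> # A tibble: 1 × 7
#>   contig   pos ref   alt   editor               correctable precise
#>   <chr>  <int> <chr> <chr> <chr>                <lgl>       <lgl>
#> 1 chr5      31 G     A     N-dRRAABE-TadA*(82G) TRUE        TRUE
res$placements[[1]][, c("strand", "pam_start", "position", "n_bystanders")]
#> # A tibble: 1 × 4
#>   strand pam_start position n_bystanders
#>   <chr>      <int>    <int>        <int>
#> 1 +             25        3            0
```

The variant is correctable (the alt A sits at protospacer position 3
of a plus-strand TTTA placement; editing A→G restores the reference)
and precisely so (no other A in the window). At cohort scale, a
simulated 100-variant pathogenic cohort with 25 planted correctable
sites (10 precise) is recovered exactly, and the table shows how the
wide-window union pseudo-editor trades precision for reach:

```r
cohort <- simulate_cohort(sim_config(seed = 1), reg, "N-dRRAABE-TadA*(82G)")
fr <- cohort_fractions(cohort$variants, reg,
                       c("N-dRRAABE-TadA*(82G)", "miniABE-any"))
dplyr::filter(fr, class == "all")
#> # A tibble: 2 × 7
#>   editor               class     n n_correctable n_precise frac_correctable frac_precise
#>   <chr>                <chr> <int>         <int>     <int>            <dbl>        <dbl>
#> 1 N-dRRAABE-TadA*(82G) all     100            25        10             0.25          0.1
#> 2 miniABE-any          all     100            28         0             0.28          0
```

Quantifying simulated amplicon reads (5,000 reads, planted C→T
frequencies 0.25 at C3 and 0.10 at C5, 96% C→T purity) recovers the
planted signal, calls the window at its half-maximum, and partitions
edited reads by outcome base:

```r
cbe <- reg[["N-d12fCBE-3A130"]]
set.seed(99)
amp <- random_dna(81); substr(amp, 17, 20) <- "TTTG"
substr(amp, 23, 23) <- "C"; substr(amp, 25, 25) <- "C"
design <- amplicon_design(amp, cbe, contig = "site1")
cfg <- sim_config(seed = 2, read_count = 5000,
                  freqs = c("3" = 0.25, "5" = 0.10),
                  purity = c(T = 0.96, G = 0.02, A = 0.02))
sim <- simulate_reads(design, cfg)
m <- tabulate_substitutions(sim$reads, design)
window_profile(m) |> dplyr::select(position, frequency, depth) |> head(3)
#> # A tibble: 3 × 3
#>   position frequency depth
#>      <int>     <dbl> <int>
#> 1        2    0.0002  5000
#> 2        3    0.241   5000
#> 3        5    0.0968  5000
call_window(aggregate_profiles(list(window_profile(m))))
#> $positions
#> [1] 3
#> $peak
#> [1] 3
product_purity(m, 23)
#> # A tibble: 3 × 3
#>   outcome count fraction
#>   <chr>   <int>    <dbl>
#> 1 C>A        29   0.0231
#> 2 C>G        24   0.0191
#> 3 C>T      1205   0.958
```

A thin command-line wrapper over the end-to-end pipeline is installed
with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package="mbescope"))')" \
  --seed 1 --out run1/
```

## Scope

The package re-implements post-sequencing analysis only: no read
mapping or variant calling (those stay with BWA/STAR/GATK-class
tools), no indel quantification, no off-target site prediction
(Cas-OFFinder-style site lists are user inputs), and no modelling of
editing-efficiency magnitudes — windows are tiered position sets, not
activity predictions. See the methods vignette
(`vignettes/minibe-methods.Rmd`) for the model, parameter and design
discussion.
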