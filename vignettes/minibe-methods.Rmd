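---
title: "Models and methods behind mbescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbescope)
```

# The objects and the model

`mbescope` treats a base editor as data, not code. A
`base_editor_spec` records the chemistry (A→G for adenine editors,
C→T for cytosine editors), the PAM as an IUPAC pattern with its side,
a coordinate convention, and the editing windows as explicit integer
*sets* of protospacer positions. Sets rather than ranges matter:
several terminal-fusion constructs have genuinely non-contiguous
windows (a peak position plus scattered flanking activity), and a
range encoding would misstate them.

Two conventions coexist because miniature Cas12f editors and
nCas9-based constructs number their protospacers differently:

* `cas12f_r_zero` — PAM (`TTTR`) 5′ of the protospacer; the final PAM
  base, the R, is position 0 and the first protospacer base is
  position 1. Window positions are therefore ≥ 1, and the anchor of a
  placement is the genomic index of the R.
* `spcas9_pam_distal` — PAM (`NGG`) 3′ of the protospacer; positions
  run 1..20 from the PAM-distal end, the usual SpCas9 numbering.

All genomic coordinates in the package are 1-based inclusive on the
plus strand, matching VCF and the way window positions are quoted in
the literature. Position arithmetic under `cas12f_r_zero` is purely
difference-based (`position = genomic_index − anchor` on the plus
strand, mirrored on the minus strand), so the choice of coordinate
origin does not affect any result.

## Scanning

`find_pam_sites()` reports every oriented PAM match on both strands
whose full protospacer (default 20 nt, configurable per spec) lies
inside the sequence. Overlapping matches are all reported;
deduplication is deliberately the caller's job, because two
overlapping placements can put the same target base at different
window positions. The matching rule is conservative for design use:
an unambiguous sequence base matches any pattern letter whose IUPAC
expansion contains it, but an `N` (or other ambiguity letter) in the
*sequence* matches only the identical pattern letter — an unknown base
is never assumed to satisfy a PAM. The scanner is a linear vectorised
scan; genome-scale indexing is out of scope (inputs are desk-scale
contigs, flanks and amplicons).

## Targetability

Correction is modelled physically. The molecule scanned is the
*alt-carrying* flank — the allele actually present in the genome to be
edited — because a variant can create or destroy its own PAM. A
variant is **correctable** by an editor iff on some strand the alt
base reads as the editor's substrate base at an activity-window
position of some placement, and the edit product equals the reference
allele. Bystanders of a placement are the other substrate bases inside
the activity window.

**Precisely correctable** is not defined quantitatively in the
literature; we operationalise it as the strictest reading consistent
with "single-base resolution": some qualifying placement puts the
target inside the precision window *and* carries zero same-chemistry
bystanders anywhere in the activity window. A relaxed mode
(`bystander_scope = "precision_window"`), which tolerates bystanders
outside the precision window, is available because the stricter and
the relaxed reading genuinely differ for editors with a narrow
precision tier inside a wide activity window.

A flank too short to prove or refute a placement raises an explicit
"undeterminable" error rather than silently returning `FALSE`; with
the default 30-nt flank radius every PAM/protospacer geometry of a
20-nt protospacer is covered on both strands. Variants whose ref/alt
pair is chemically unreachable on either strand are classified
`FALSE` without needing the flank at all.

`cohort_fractions()` reports numerators and denominators alongside
each fraction, always includes the four transition classes (A>G, C>T,
G>A, T>C) plus an `all` row, and reports empty classes as `NA`
(undefined), never 0. The mapping between variant classes and
chemistries (an A>G variant is corrected by a cytosine editor via the
opposite strand, a G>A variant by an adenine editor) is *not*
hard-coded anywhere: the full class × editor table is emitted and the
reader slices it, because published cohort percentages are ambiguous
about which convention they count under.

Installation design ranks candidate placements by (1) target inside
the precision window, (2) fewer bystanders, (3) target at a preferred
position, (4) smaller position number. The ranking is lexicographic
and total given the uniform tie-break (smallest position), so results
are reproducible.

## Amplicon quantification

The read model is gapless: reads are full-length copies of the
amplicon reference, and any read of deviating length is rejected and
counted (more than 50% rejections is a hard error). This matches the
package's scope — substitution-level quantification of base-editing
outcomes; indel calling, trimming/merging and base-quality-aware
calling are out of scope, and base qualities are ignored throughout.

Every statistic derives from the per-position substitution matrix.
`N` calls are excluded from the informative depth position-wise.
Editing profiles are defined only at positions whose reference base
(on the placement strand) is the substrate base; *absent is not zero*,
and aggregation across sites excludes absent positions from both
numerator and denominator. Window calling uses a half-maximum rule
(positions with mean ≥ `threshold_fraction` × max, default 0.5) with
the peak at the argmax. Product purity partitions *edited* reads
(any non-reference call at the queried position) by outcome base;
zero edited reads yields an explicitly flagged undefined result, never
a silent zero. On/off-target ratios floor zero observed off-target
editing at one read (`1/off_depth`) and flag the flooring, keeping
ratios finite without hiding the censoring. Ties everywhere —
window peaks, R-loop maxima — resolve to the smallest
position/coordinate; this is stated once and applied uniformly.

Frequencies can be suppressed below a configurable informative-depth
minimum (`min_depth`); the default is 1 so that small unit-test
matrices are fully visible, and ~100 is a sensible choice for real
amplicon data.

## Variant-call hard filtering

The RNA-editing filter is the five-clause disjunction
`QUAL < 25 || MQ < 20.0 || QD < 2.0 || FS > 30.0 || DP < 20`, applied
to caller output records; boundary values pass because the
inequalities are strict. A missing field fails the record with an
explicit `missing:<field>` reason. Without transcript annotation the
strand of an RNA edit is unknowable from the call alone, so A>G and
T>C are pooled as the A-to-I class (likewise C>T/G>A as C-to-U), and
the full 12-class transition table is exposed for annotation-aware
re-slicing. A position-level set-difference helper
(`subtract_parent()`) supports comparisons against a parent sample;
whether to subtract shared germline calls is left to the caller.

# The simulator: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with ground
truth attached, under a single mandatory seed (fixed per-generator
offsets derive sub-streams, so one config can feed several generators
without correlated draws; identical configs reproduce byte-identical
FASTA/FASTQ/VCF files).

* `simulate_cohort()` emulates a pathogenic-SNV cohort: uniform
  GC-neutral background flanks, with exactly the planted numbers of
  correctable and precisely-correctable variants built by inverse
  construction (choose a target position in or out of the window,
  plant or withhold the PAM and bystanders, mirror to the minus strand
  with probability 1/2). Uniform background occasionally creates
  incidental PAM placements that would flip a verdict, so each
  constructed flank is verified with the package classifier and
  redrawn until the verdict matches the intent. This verification is
  not circular: the classifier itself is validated against an
  independent brute-force oracle in the test suite, on variants that
  include these same construction patterns.
* `simulate_reads()` emulates targeted amplicon sequencing: per-read
  editing under either an *independent* model (each substrate position
  converts independently at its planted frequency, outcome base drawn
  from a purity mix) or a *linked* model (one latent edited state per
  read converts all planted positions to the pure canonical product —
  the idealisation of concerted processive editing, and the model
  under which allele-level truth is exact when the error rate is 0),
  followed by uniform per-base substitution error (default 1e-3,
  an Illumina-like magnitude). Default read depth is 5,000.
* `simulate_called_variants()` plants records that pass the hard
  filter or fail exactly one named clause, with field values drawn
  uniformly from the relevant pass/fail ranges.

What the simulator deliberately does **not** emulate: indels and
length variation, position- or context-dependent error models, base
qualities, PCR duplicates and strand bias, linkage between editing and
sequencing errors, and any real distribution of clinical variants
around PAMs. Consequently, passing tests demonstrate correctness of
the *computations* (counting, geometry, set logic, conservation) under
a clean generative model — they do not validate performance on real
sequencing artefacts, which is why the quantification deliberately
re-implements only substitution counting and leaves read processing to
dedicated tools.

# Numerical and testing choices

Problem sizes in the verification suite were chosen to make binomial
noise negligible relative to the asserted tolerances while keeping the
default test run fast: 200 random 2-kb sequences for scanner/oracle
equivalence, 500 random variants for classifier/oracle equivalence,
10 seeds × 100-variant cohorts for exact planted-fraction recovery,
20 seeds × 5,000 reads for frequency recovery within 3 binomial
standard errors, and 1,000 randomized records (plus explicit boundary
records) for the filter truth table. Discrete verdicts are compared
exactly; only frequency recovery uses a stochastic bound.

Known limitations, beyond the simulator's scope above: protospacer
length is assumed 20 nt by default for all constructs (configurable
per spec, since guide architectures vary); the union pseudo-editors
(`miniABE-any`, `miniCBE-any`) take their precision window equal to
their activity window, so "precise" is only meaningful for concrete
editors; and the registry's window tiers for constructs with marginal
flanking activity (e.g. an A18–A19 shoulder next to an A16–A17
window) encode both tiers — activity includes the shoulder, precision
does not — so consumers choose which tier their analysis needs.
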