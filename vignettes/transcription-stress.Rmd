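---
title: "Quantifying transcription stress and chromosome fragility with txstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription stress and chromosome fragility with txstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txstress)
library(GenomicRanges)
```

# Background

Loss of the R-loop helicase senataxin (SETX) has two measurable genomic
signatures: RNA polymerase II accumulates in promoter-proximal regions
(pausing, or "transcription stress"), preferentially at promoters whose
transcribed strand is G-rich (high GC skew, the R-loop-favoring
orientation); and the genome accumulates copy-number changes (CNCs) that
overlap fragile-site region sets more often than chance. `txstress`
implements the statistics behind both observations, plus the qPCR
arithmetic used to validate individual loci, and a synthetic-data
generator that emulates the inputs so every claim the package makes can
be tested end-to-end offline.

This vignette explains the models and conventions, the tunable parameters
and their defaults, what the generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result beyond what the package's tests and acceptance script
themselves compute.

# Coordinates and containers

All coordinates inside the package are 1-based and closed — the native
`GRanges` convention — and region sets, coverage and sequence live in the
standard Bioconductor containers (`GRanges`, `RleList`, `DNAStringSet`,
`Seqinfo`). BED and bedGraph files are 0-based half-open on disk;
`read_bed()`/`read_bedgraph()` and the writers delegate the conversion to
`rtracklayer`, so no hand-written offset arithmetic exists anywhere.
Gene models are plain data frames (`gene_id`, `chrom`, `strand`, `tss`,
`tes`, 1-based), with `tss > tes` on the minus strand; `length_bp` is the
inclusive span `|tes − tss| + 1`.

# Permutation enrichment of region sets

The observed statistic is `overlap_kb(query, features)`: total base pairs
shared by the merged coverages of the two sets, divided by 1,000. Merging
first means multiply-covered bases count once and the statistic is
symmetric.

The null model (`randomize_regions()`) re-places each query interval
uniformly among the start positions at which it fits on **its own
chromosome**, outside an optional mask of excluded regions. Interval
count, the multiset of lengths, and chromosome assignments are conserved;
placements are independent, so permuted intervals may overlap each other
(they are merged before the overlap is measured, exactly as the observed
set is). Chromosome-preserving placement is the stricter and more common
null for copy-number data, since aCGH sensitivity and chromosome content
differ between chromosomes; a genome-wide placement null would only widen
the null distribution.

Two p-values are reported, and the distinction matters:

* `p_empirical` = (1 + #{null ≥ observed, in the observed direction}) /
  (n_perm + 1). It is floored at 1/(n_perm + 1): with the default 1,000
  permutations it can never go below ~0.001.
* `p_value`, from the z-score of the observed overlap against the null
  mean and standard deviation (two-sided by default; one-sided behind a
  flag). Only this parametric tail can express enrichments much stronger
  than the permutation floor — which is how overlap p-values in the 1e-6
  to 1e-30 range arise from 1,000 permutations. It assumes the null is
  approximately normal, which holds for sums of many interval overlaps
  but not for degenerate designs; the tests check the two routes agree
  within a factor of 3 in the mid-range.

When the null has zero variance (e.g. features covering every base), the
result is flagged `degenerate`: the z-based p is reported missing and the
empirical p stands. Direction (`enrichment`/`depletion`) is always the
sign of observed minus null mean, reported separately from the p-value.

`expression_overlap_test()` reuses the same null but counts
differentially expressed **genes** overlapped (≥ 1 bp with the gene body)
instead of kilobases — gene membership is effectively point-like relative
to CNC sizes, so a kb statistic would be dominated by gene length rather
than gene count.

The permutation loop runs on plain integer vectors with prefix-sum
overlap lookups; the test suite asserts this fast route equals
`overlap_kb()` exactly on random draws, so the hot path and the public
statistic cannot drift apart.

# CNC calling, replicate intersection, annotation

The array-CGH caller (`call_cnc()`) is deliberately minimal: a gain is a
maximal run of at least `min_probes` (default 5) consecutive probes with
log2 ratio ≥ `threshold_log2` (default 0.5), a loss the mirror image, and
the call spans the first to last probe of the run. It is deterministic
and checkable probe-by-probe, which is what the downstream statistics
need; it is **not** a reimplementation of any vendor segmentation
algorithm, and makes no claim of matching one. With the defaults, a
noiseless embedded segment of amplitude 1.0 and ≥ 10 probes is recovered
with boundary error bounded by one probe spacing, and i.i.d. noise of
sd 0.1 essentially never produces a call (the per-window run probability
is bounded by P(|N(0, 0.1)| ≥ 0.5)^5 ≈ 3e-30 per 5-probe window).

Replicate intersection ("common to both experiments") keeps the intervals
of one replicate that overlap a same-class interval of the other by at
least 1 bp; a minimum reciprocal fraction is available
(`min_overlap_frac`) but defaults to 0, since no published overlap
fraction exists to calibrate against.

Region annotation offers nearest-TSS distance — measured from the region
**midpoint** by default (edge mode behind a flag), reported in kb, `NA`
(not zero) on geneless chromosomes — and a genes-per-region count of TSSs
within the region extended by `window_bp`. The window count is an
explicitly simplified stand-in for regulatory-domain tools like GREAT and
is documented as not reproducing their assignments.

# Traveling ratio and RoTR

For a gene on the plus strand with TSS t, the promoter-proximal window is
[t − 30, t + 300) in transcription coordinates (330 bp) and the gene body
is [t + 300, TES]; minus-strand genes use the mirror-image windows, so a
reverse-complemented genome yields identical values (asserted in tests).
The traveling ratio is

TR = (promoter density + pseudocount) / (body density + pseudocount),

with densities in signal per bp computed from the per-base `RleList`
track (bedGraph intervals are represented exactly, so there is no binning
error; partial windows are impossible by construction). The pseudocount
defaults to 0, in which case genes with zero body density are excluded
with a recorded reason, as are genes whose TES lies within the promoter
window (body would be empty) and genes whose windows leave the coverage
extent. Exclusion reasons are kept per gene because silent filtering is
exactly how active-gene counts become unreproducible.

RoTR is TR(ChIP)/TR(input) per gene within a condition; the same function
(`ratio_of_traveling_ratios()`) serves the mutant/wild-type mode by
passing two ChIP tables. The choice of which ratio a cumulative curve
shows is the caller's; the package default (ChIP/input) normalizes each
condition by its own input before conditions are compared.

Active genes — the analog of "genes with clear promoter-proximal RNAPII
peaks" — are called by two explicit thresholds: ChIP promoter density ≥
`min_promoter_density` (default 0.25 signal/bp) and ChIP/input promoter
enrichment ≥ `enrichment_threshold` (default 2). The defaults were chosen
once so that the generator's expressed genes (body rate 0.5/bp against an
input of 0.2/bp) are recovered at ≥ 99% with no false calls, and are
plainly not a calibrated reanalysis of any published active-gene count.

`compare_distributions()` is a two-sided Wilcoxon rank-sum test. With
both samples ≤ 8 observations it enumerates all C(n1+n2, n1) group
assignments — which remains exact under ties, where the classical exact
distribution does not apply — and reports
p = min(1, 2·min(P(U ≤ u), P(U ≥ u))). Larger samples use mid-ranks and
the tie-corrected normal variance without continuity correction. The
metagene profile (`metagene_profile()`) rescales each strand-oriented
gene body to a fixed bin count by averaging (exact for piecewise-constant
signal) and averages across genes.

# GC skew and stratification

`gc_skew()` returns (G − C)/(G + C) on the transcribed strand:
minus-strand sequences are reverse-complemented before counting, so a
positive value always means a G-rich non-template strand — the
orientation that stabilizes R-loops. N bases are ignored; G + C = 0 is
`NA` and flagged, as are intervals more than half N. Skew can be measured
over the full genic interval or the promoter-proximal window; both modes
exist because either could underlie a published genic-interval skew
distribution, and the choice is left explicit.

Stratification takes the 10% and 90% empirical quantiles of the **full**
gene universe (R's default type-7 quantile; with 100 distinct values this
yields tails of exactly 10 genes each), assigns `low` = skew ≤ q10 and
`high` = skew ≥ q90, then intersects with the active-gene set. With
heavily tied skew values the tails can be much larger than 10% — the
quantile rule, not the package, decides that, which is why the rule is
documented. Length stratification splits at 100 kb (boundary genes,
exactly 100,000 bp, go to `short`, since the strict inequalities of the
usual phrasing leave the boundary open) or into 20%/40–60%/20% quantile
groups.

# qPCR quantification

All quantities are closed forms of mean technical-replicate Ct values:
2^−ΔΔCt; percent input = 100 · 2^((Ct_input − log2(1/f)) − Ct_IP) for
input fraction f (default 0.01); fold enrichment = percent(specific) /
percent(IgG); DRIP relative value = percent(target) / percent(negative
control region) within the same sample (the within-sample division is the
default; normalizing to a control sample instead is a caller-side
variation). Replicates are summarized by the mean, flagged when their
range exceeds 0.5 cycles; zero denominators flag the record rather than
dividing. A global one-cycle shift of every Ct leaves all ratios
unchanged, and the ratios are invariant to the input fraction — both
asserted as tests. Biological replicates are reported as mean ± SEM
(`replicate_sem()`), matching the usual presentation of qPCR panels.

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
with one deterministic stream per seed:

* **Genome and genes** — uniform-random ACGT chromosomes (default
  2 × 5 Mb); 300 genes with log-normal lengths (meanlog = log 8000,
  sdlog = 0.6, clamped to 1–200 kb), placed without overlap on both
  strands with ≥ 400 bp between neighbors. Each gene's promoter window is
  rewritten with a fixed base composition hitting its assigned skew class
  (+0.4 "high" or −0.2 "low" at GC fraction 0.5) to within rounding — the
  composition is deterministic and only the arrangement is random, so the
  realized skew is within ±0.05 of target by construction rather than by
  sampling luck.
* **Coverage** — expressed genes (default 70%) carry body rate
  λ = 0.5 signal/bp and promoter rate λ·π, where π is the pausing factor
  (2 for wild type, 4 for knockout by default); background 0.02/bp;
  input is uniform 0.2/bp. Counts are Poisson per 10-bp bin, reported as
  signal per bp, so the expected TR of an expressed gene is approximately
  π (exactly (bg + λπ)/(bg + λ)). The default pipeline scenario couples
  the knockout pausing factor to the skew class — high-skew promoters
  pause more on SETX loss — because that coupling is the phenomenon the
  stratified comparison exists to detect.
* **CNCs and features** — 25 feature intervals of 20 kb (≈ 5% of the
  genome) and 50 CNCs of 2 kb, a configurable fraction planted wholly
  inside features; CNCs are redrawn until separated by at least two probe
  spacings, since real CNC calls are disjoint and unseparated planted
  segments would merge in the probe track. The probe table (200-bp
  spacing, Gaussian noise sd 0.1) carries each CNC as a ±1.0 log2
  segment.
* **qPCR** — Ct = base − log2(abundance) + N(0, 0.1 cycles), three
  technical replicates.

What the generator does **not** emulate: mappability and GC bias in
coverage, fragment-size effects, overdispersion beyond Poisson,
chromatin-accessibility structure in the permutation space, array
dye-bias or wave artifacts, and amplification-efficiency differences in
qPCR. Passing tests therefore demonstrate that the statistics are
implemented correctly and are well-calibrated under their stated
assumptions — not that those assumptions hold in any particular real
dataset.

# Problem sizes and numerical choices

The test and acceptance simulations use the desk-scale defaults —
10 Mb genomes, 300 genes, 50 CNCs, 200–1,000 permutations, 100–1,000
replicate runs — sizes chosen so the full suite completes in minutes
while every statistical check retains comfortable resolution (e.g. the
calibration check uses 500 independent tests, whose exact binomial 99%
band around a 5% rejection rate is the pass criterion). Other numerical
choices: permutation draws use one uniform per interval (placement among
valid starts is exactly uniform, including masked layouts, via
cumulative valid-start counts); merged-interval arithmetic is integer
throughout; the Wilcoxon exact path switches on at n ≤ 8 per sample
(12,870 assignments at worst); quantile ties follow R's type-7
interpolation; and every public randomized function takes an explicit
seed and records it in its result.

# Known limitations

* The z-based permutation p-value relies on approximate normality of the
  null; for very few or very large query intervals prefer `p_empirical`
  and more permutations.
* The CNC caller does not model probe-level variance heterogeneity or
  segment amplitudes near the threshold; it is a testing-grade caller,
  not a clinical one.
* The genes-per-region window rule is not a regulatory-domain model;
  counts are not comparable to GREAT output.
* Active-gene calling and the GC-skew group sizes depend visibly on
  their thresholds and on tie structure; both are parameters, not
  constants of nature, and the pipeline logs them with every run.
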