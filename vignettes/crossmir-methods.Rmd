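---
title: "Methods: cross-platform small RNA biomarker analysis with crossmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform small RNA biomarker analysis with crossmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmir)
```

## The problem

Circulating miRNAs (18–25 nt regulatory RNAs measured in whole blood) are
attractive disease biomarkers, but candidates discovered by small RNA
sequencing frequently fail to validate by RT-qPCR. Two technical causes
dominate. First, differential-expression calls are sensitive to the
normalisation applied to sequencing counts. Second, mature-miRNA qPCR
assays cross-detect precursor hairpins that are still present in total RNA
but are removed (by gel size selection) before sequencing library
preparation, so the two platforms do not even measure the same molecular
pool unless the qPCR input is size-selected too.

`crossmir` implements a pipeline that addresses both: a *consensus*
differential-expression test that only calls a transcript when three
different normalisations agree, and an absolute-quantification qPCR arm in
which small-RNA enrichment removes precursor signal and an exogenous
spike-in corrects for the material lost in the process.

## Sequencing arm

### Read cleanup and unique tags

Reads are 3'-adapter trimmed (leftmost adapter-prefix hit of at least
`min_overlap = 7` nt, at most 10% mismatching bases within the overlap),
then filtered to 18–25 nt inclusive, then collapsed to unique sequence
tags with per-sample counts. Reads without a detectable adapter are kept:
exclusion is by length, not by adapter presence, since a full-length
insert can legitimately fill the whole read. The trimming parameters are
conventional small-RNA values; they are exposed in the run configuration
because the upstream tools this step replaces do not document a single
standard. Quality-based trimming is deliberately omitted — the synthetic
reads carry no meaningful quality signal, and the length filter is what
the downstream contract depends on.

### IsomiR-tolerant annotation

A tag is accepted as an isomiR of a mature reference if some ungapped
placement puts both ends within ±2 nt of the mature ends with at most one
mismatching base. Per-end offsets are defined as `offset5 = tag start −
mature start` (negative = 5' extension) and `offset3 = tag end − mature
end` (positive = 3' extension). Two readings of the tolerance were
possible; we resolved them as follows and treat them as part of the
method's definition:

* the ±2 limit applies *per end*, so a tag may be shifted by 2 at both
  ends simultaneously;
* the single allowed mismatch may itself lie in an extension: an
  extension base is compared against precursor flanking sequence when a
  precursor containing the mature sequence is supplied, and is charged as
  a mismatch otherwise (without context, templated and non-templated
  additions are indistinguishable, and the common biological case — a
  single non-templated 3' adenine — should still be accepted).

A tag matching several references contributes its full count to each of
them (multi-mapped tags are associated with all their references, not
fractionally split). Library sizes are therefore taken from the cleaned
read totals, never from count-matrix column sums, which would
double-count multi-mapped tags. Ties between equally good placements are
broken deterministically: fewest mismatches, then smallest total shift
`|offset5| + |offset3|`, then lexicographic reference id.

### Normalisation

Three methods are computed on the CPM-filtered matrix (≥ 1 count per
million in ≥ 3 samples):

* **RPKM**: `count · 10⁹ / (length · library size)`. The transcript
  length is the mature reference length; as a per-transcript constant it
  cancels from fold changes and t-statistics.
* **Quantile**: in `full` mode each sample's order statistics are
  replaced by the cross-sample mean order statistics; tied counts receive
  the *mean of the quantiles they span*, which keeps column means exactly
  equal (interpolating at average ranks, as some implementations do, does
  not). An `upper_quartile` mode divides each sample by its 75th
  percentile of nonzero counts scaled to geometric mean 1; both modes are
  first-class because the two conventions circulate under the same name
  in the literature, and the choice is recorded in the run
  configuration (`full` is the default).
* **TMM**: pairwise trimmed mean of M-values against a reference sample
  (the one whose 75th percentile of scaled counts is closest to the
  mean), trimming 30% of M and 5% of A on each side, with inverse
  delta-method precision weights, factors centred to geometric mean 1.
  These are the original method's published defaults. When fewer than 10
  transcripts survive the trims the untrimmed weighted mean is used with
  a warning — small miRNA panels reach this regime quickly.

### Consensus testing, effect size and power

Per normalisation, each transcript gets a Welch (unequal-variance) t-test
between groups; two-tailed p-values are Benjamini–Hochberg adjusted
*within* each normalisation across the filtered transcript set (the
adjustment universe is a free choice; adjusting within method keeps the
three branches symmetric). A transcript is consensus-significant only if
`q < alpha` under all three normalisations — an intersection that trades
sensitivity for specificity and whose false-positive rate is bounded by
each branch's. Ranks are assigned per method by ascending p, ties broken
by descending `|t|` then transcript id. Transcripts observed exclusively
in one group are reported separately and only when their total count is
at least 10, to exclude sequencing artifacts.

Effect sizes use Cohen's d with the *average-SD* denominator,
`d = (m₁ − m₂) / ((s₁ + s₂)/2)`. This choice was reverse-engineered: the
published summary table this package reconstructs is reproduced exactly
by the average-SD form (e.g. `(845 − 368)/((528 + 379)/2) = 1.05`) and
not by the classical pooled SD; the classical form remains available via
`sd_method = "pooled"`. Power is the exact noncentral-t rejection
probability of a two-tailed two-sample t-test with noncentrality
`d·√(n₁n₂/(n₁+n₂))` and `n₁+n₂−2` degrees of freedom — the equal-variance
df convention standard in power software, which matches the published
power values even though the test itself is Welch.

## qPCR arm

### Standard curves and absolute quantification

Each assay's dilution series is fit by ordinary least squares of Cq on
log₁₀(copies). Amplification efficiency is `E = 10^(−1/slope)` (ideal 2 —
one doubling per cycle); curves pass QC when `1.8 ≤ E ≤ 2.1`. A QC
failure warns and blocks quantification unless explicitly overridden —
the bounds describe acceptable assays rather than a hard physical limit.
Technical triplicates are combined by arithmetic mean of Cq *before*
conversion (Cq is already a log-scale quantity, so mean-Cq is log-domain
averaging); copies follow as `10^((Cq − intercept)/slope)`, with values
outside the calibrated Cq range flagged as extrapolated.

### Spike-in enrichment-process normalisation

An exogenous plant miRNA spiked into every sample at a fixed
concentration before size selection tracks per-sample recovery. Within
each RNA fraction the median spike Cq defines expected recovery and each
sample is corrected by `NF = E_spike^(Cq_sample − median)`; a sample whose
spike came up one cycle late (half the material recovered, at E = 2) has
its copies doubled. The exponential-in-efficiency form is a
reconstruction — the procedure this package follows states the medians
used but not the formula — and is the standard Cq→quantity relation,
reducing to exact doublings at E = 2. Medians are taken *per fraction*
(total vs enriched), so the factor corrects within-fraction recovery
variation while deliberately leaving the systematic enrichment loss
visible: that loss is exactly what the enrichment-impact report measures.

Group comparisons report Welch t-tests on copies and a signed fold
change: `+mean_case/mean_control` when cases are higher,
`−mean_control/mean_case` when lower, so an x-fold decrease prints as
−x, matching the reporting convention of the cohort tables shipped in
`inst/extdata`.

## The synthetic-data generator

`sim_spec()` fixes the study conditions all tests run under; its defaults
are chosen once to emulate the cohort data this pipeline targets:

* **Design**: 26 control and 15 case samples — the group sizes used in
  the published differential-expression tables this package reconstructs.
  The same simulated cohort feeds both platforms so concordance can be
  evaluated.
* **Expression profile**: one dominant miRNA at 60% of reads, runners-up
  at 13% and 3%, the rest uniform — the observed whole-blood pattern in
  which a single erythroid miRNA dominates the library.
* **Counts**: negative-binomial with dispersion 0.1 (variance
  `μ + 0.1μ²`), a typical bulk-RNA biological dispersion; the true
  differential target is down 2.3-fold in cases, the fold change the
  reconstructed tables report for their top candidate.
* **IsomiRs**: 83.1% canonical sequence, 13.8% with one extra 3'
  nucleotide (templated from the precursor when one exists, else a
  non-templated A), 3.1% other variants — the observed isoform mixture
  for the top candidate miRNA.
* **Library depth**: 20,000 reads per sample. This is deliberately
  scaled down from real sequencing depth so that full pipeline runs stay
  interactive; all count-level behaviour scales linearly with it, and
  the package's recovery checks hold at this depth.
* **qPCR**: slope −3.3219 (E = 2), intercept 40 cycles, replicate noise
  0.25 cycles; spike input 1.2×10⁷ copies/µl; enrichment recovery 0.048,
  chosen so the spike-in Cq shift between fractions is ≈ 4.4 cycles,
  matching the published medians (27.4 → 31.78); between-sample
  biological copy variation log-normal with log-SD 0.8 (CV ≈ 1, the
  order observed in the cohort copy-number tables); per-sample
  processing recovery jitter with CV 0.3 applied to all assays including
  the spike, which is the variation spike-in normalisation exists to
  remove.
* **Precursor contamination**: in the total-RNA fraction the mature
  assay detects `mature + 0.5 × precursor` copies; the enriched fraction
  detects `recovery × mature` only. The 0.5 detection fraction and the
  non-dysregulated precursor pool (mean 8×10⁷ copies) are free
  parameters: the underlying study demonstrates the cross-detection
  mechanism but does not quantify the precursor:mature ratio in blood,
  so the generator exposes rather than asserts these values.

All generators are deterministic under the single spec seed; each stage
draws from a fixed offset of it (reference +101, reads +202, copies
+303, Cq +404) so stages can be re-run independently and byte-identical
outputs are a tested invariant.

What the generator does *not* emulate: sequencing error beyond the
isomiR substitution structure, quality-score realism, GC bias, adapter
dimers, or genuinely unknown small RNAs. Passing tests therefore
demonstrate correctness of the pipeline's algorithms under the stated
statistical model, not robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

* Variances computed row-wise via sums of squares are clamped at zero;
  quantile normalisation can make a transcript exactly constant across
  samples, and round-off would otherwise produce a negative variance and
  a NaN t-statistic. Degenerate rows (both group variances zero) get
  `t = 0, p = 1` when means agree and `p = 0` otherwise; the scalar
  `welch_t()` refuses them instead, as a contract violation.
* Efficiency QC applies a 10⁻⁹ epsilon at the 1.8/2.1 bounds so curves
  sitting numerically on a bound pass.
* BH adjustment, Welch tests on raw vectors, and noncentral-t
  probabilities delegate to `stats::p.adjust`, `stats::t.test` and
  `stats::pt`; the package re-derives none of them, but its test suite
  checks each against an independent brute-force or closed-form oracle.
* TMM and full-quantile normalisation are implemented here (they are
  part of the package's consensus contribution) and are cross-checked in
  the test suite against the independent `edgeR` and `limma`
  implementations — within 1% for TMM on random negative-binomial
  matrices, exactly for quantile on tie-free input.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data: consensus false-positive
rates use 500 null simulations of a 40-transcript, 8 + 8 design; the
cross-platform recovery check runs the full read-level pipeline on ten
seeds of the default 26 + 15 design at 20,000 reads per sample; oracle
comparisons use 50 random matrices (TMM) and ~80-tag/10-reference
instances (isomiR matching). These sizes were chosen as the smallest at
which each property is comfortably identified.

## Known limitations

* The consensus test treats the three normalisations symmetrically;
  it does not model their dependence, so its realised false-discovery
  rate is conservative rather than exactly `alpha`.
* Annotation is reference-bound: novel miRNAs, tRNA fragments and other
  small RNAs end up in the unannotated set without further
  classification.
* The spike-in normalisation assumes the spike recovers like an
  endogenous mature miRNA of similar size; systematic spike-specific
  losses would bias all samples equally and cancel from group
  comparisons, but not from absolute copy numbers.
* Absolute copy numbers from total RNA remain upper bounds in the
  presence of precursor cross-detection; only enriched-fraction values
  should be interpreted as mature-miRNA copies.
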