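---
title: "Methods: comparative enrichment analysis of co-precipitation experiments"
author: "coPrecip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative enrichment analysis of co-precipitation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coPrecip)
```

# Scope and scientific background

Trypanosomatids such as *Trypanosoma brucei* carry several eIF4F-like
cap-binding complexes built from paralogous eIF4E and eIF4G subunits. Two of
them — EIF4E3/EIF4G4 and EIF4E4/EIF4G3 — are the best candidates for
general translation initiation, and their functional differentiation can be
probed on two axes: which *proteins* co-precipitate with each tagged subunit
(AP-MS co-IP against a negative-control bait), and which *mRNAs*
co-precipitate with each cap-binding eIF4E (RIP-/CLIP-seq against a
negative control). `coPrecip` implements the downstream comparative
analyses for both axes: ratio-to-control scoring of label-free MS
intensities with fold-change tiers, interactome set arithmetic and
functional-category summaries, and transcript-level enrichment with
TPM/RPKM abundance measures and a replicate-aware beta-binomial test.
Upstream steps (peptide identification, read mapping and counting) are out
of scope; the package consumes protein-level intensity matrices and
transcript-level count matrices.

# AP-MS scoring model

One immunoprecipitation batch consists of all samples quantified together —
for the canonical design, four tagged baits plus one negative-control bait,
each in biological triplicate (15 samples). Scoring proceeds in four steps:

1. **Batch normalization** (`normalizeByTotal`): each sample is scaled by
   (largest total intensity in the batch) / (its own total), so every
   sample total equals the batch maximum. Zeros (non-detections) stay
   zero. The operation is idempotent and rescaling any one sample by a
   positive constant leaves all downstream ratios unchanged.
2. **Replicate averaging** (`conditionMeans`): the arithmetic mean over all
   replicates of a condition, with non-detections entering as 0. No
   imputation is performed; a protein seen once at intensity 6 in a
   triplicate averages to 2. This is the simplest reading of
   "average of the replicates" and makes the dropout process visible to
   the downstream filters rather than hiding it.
3. **Enrichment ratio** (`enrichmentRatio`): bait mean ÷ control mean.
   When the control mean is zero and the bait mean positive the ratio is
   reported as `Inf` — the enrichment is unquantifiable but clearly
   present, so `Inf` passes every fold threshold and sorts above all
   finite ratios. When both means are zero the ratio is undefined (`NaN`);
   such rows are never reported and are omitted from output files (the run
   log counts them).
4. **Filters and tiers** (`peptideSupport`, `assignTiers`): a protein is
   *reported* for a bait when its ratio is at least 2 (inclusive; `Inf`
   qualifies) and at least two of that bait condition's replicates
   identified it with at least two peptides. Fold tiers follow the
   reporting conventions of the motivating studies: `low` above 1.5,
   `highlight` strictly above 4, and `top` strictly above 8 with a bait
   mean intensity above `intensity_floor` (default `1e6`, arbitrary LFQ
   units). The reporting bound is inclusive and the tier bounds strict,
   mirroring the "2-fold or more" versus "ratio >4" / ">8" wording they
   implement. Ties in ranking are broken by descending bait mean and then
   protein ID, so outputs are deterministic.

The peptide rule is evaluated per (protein, bait condition) on that
condition's replicates only; whether the counts are unique, razor or total
peptides is up to the table supplied.

# Interactome comparisons

`baitSets` extracts the per-bait reported sets; `exclusivity` computes, for
each bait, the number and fraction of its set found with no other bait and
the pairwise shared counts (symmetric by construction). `pairwiseEnrichment`
compares two baits from the *same* normalized batch protein by protein
with the same `Inf`/`NaN` ratio convention — no re-normalization per pair —
flagging proteins enriched in either direction at a configurable fold.

`categorize` reproduces, as an explicit ordered rule set, the kind of
manual GO-based functional grouping used in interactome tables: ordered,
case-insensitive regular-expression rules with first-match-wins semantics
and an "Undefined Function" fallback that guarantees total coverage (so
category fractions always sum to 1). The default rules put the ribosomal
protein pattern first (substring `"ribosomal protein"`, deliberately
including organellar ribosomal proteins), and match kinases/phosphatases
before the generic RNA-binding and enzyme patterns and chaperones and
transport factors before enzymes — otherwise names like "casein kinase" or
"valosin-containing protein" would be swallowed by broader patterns. A
manual classification cannot be recovered exactly for every entry; the rule
set is a reproducible approximation, user-replaceable via
`readCategoryRules`, and only the ribosomal count and the fallback are
anchored to published tables in the test suite.

# Transcript enrichment

Both sequencing arms start from raw per-transcript read counts with
transcript lengths and raw column totals as library sizes (no TMM or
quantile scaling — the upstream protocols used none).

* **Abundance**: TPM (`tpm`), which sums to $10^6$ per sample, is the
  primary abundance measure; RPKM (`rpkm`) is computed for the SOLiD-arm
  floor. The log2 enrichment is the base-2 log of the ratio of group-mean
  TPM (IP over control) with *no pseudocount*: a zero control mean with a
  positive IP mean gives `Inf`, which passes the fold filters —
  deliberately consistent with the MS-arm convention.
* **CLIP filter** (`clipFilter`): IP-group mean raw reads ≥ 50 (the floor
  is read against the precipitated fraction, inclusively) and log2 ratio
  > 1.
* **SOLiD filter** (`solidFilter`): BH-adjusted q ≤ 0.01, IP-group mean
  RPKM ≥ 50, log2 ratio > 1.

## The beta-binomial test

`baggerlyTest` implements the weighted-proportions beta-binomial test of
the Baggerly lineage for replicated count data. For each group the
replicate proportions $p_i = x_i/n_i$ are combined with weights
$w_i = 1/\bigl(\hat p(1-\hat p)/n_i + \hat\sigma^2\bigr)$, where the first
term is binomial sampling variance and $\hat\sigma^2$ a method-of-moments
estimate (truncated at zero) of the between-replicate variance component.
The statistic is the difference of weighted group proportions over its
pooled standard error. The reference is a t distribution with
Satterthwaite-style degrees of freedom in which *only the estimated
between-replicate component consumes degrees of freedom*: when no
extra-binomial variation is estimated the binomial variance is known, the
df are infinite and the test reduces exactly to the unpooled two-proportion
z-test — the correct Poisson-limit behaviour.

With three replicates a per-transcript variance estimate has at most two
degrees of freedom per group, which caps how small a p-value any honest
per-transcript test can produce (roughly $10^{-3}$) — too coarse for FDR
control at 1% across thousands of transcripts. `ripEnrichment` therefore
pools, by default, the between-replicate dispersion across all transcripts
on the squared coefficient-of-variation scale
($\sigma^2_g = \hat\varphi\, p_g^2$, the standard negative-binomial-style
assumption, estimated as the mean of the raw per-transcript moment
estimates over both groups) and supplies it to the test as known, giving a
normal reference. This is the same remedy the field's count-based tools
(edgeR, DESeq2) adopt for small replicate numbers. Under a simulated
overdispersed null this pooled test is well calibrated (type-I error at
5% within Monte-Carlo noise, p-values uniform), while the per-transcript
form (`dispersion = "per-transcript"`) remains available and is the
exported single-transcript behaviour.

## Multiple testing

`bhFdr` applies Benjamini–Hochberg step-up adjustment (delegating to
`stats::p.adjust`; an independent brute-force step-up implementation
serves as the test oracle). BH was fixed as the FDR procedure; the
upstream protocols state only that an FDR-corrected threshold was used.

# The synthetic-data generator

Real deposits for these experiments are raw MS spectra and sequencing
reads; desk-scale reanalysis is not possible. The generator produces data
with exactly the statistical structure the scoring assumes, plus ground
truth, so every stage is testable end to end.

**AP-MS** (`simulateIpms`): background protein intensities are log-normal
(default median `1e6` arbitrary LFQ units, `baseline_log_sd = 0.12`,
i.e. ~12% replicate CV, in line with typical label-free replicate
variability); a true partner of bait B gets a multiplicative
`enrichment_fold` (default 8) boost in B's samples only; the control bait
is pure background. Non-detection is independent Bernoulli zeroing after
the draw (`dropout_prob = 0.1`), matching the "zero intensity =
not detected" semantics of LFQ tables, and peptide counts are
`1 + Poisson(peptide_rate - 1)` where detected and 0 otherwise — so the
peptide-support filter is exercised by dropout rather than by an
independent mechanism. Defaults: 2000 background proteins, 50 partners per
bait, four baits plus control, triplicates. Note that under these
conditions the `Inf`-ratio convention is the dominant source of false
highlight-tier calls: a background protein whose three control replicates
all drop out (probability $10^{-3}$) is `Inf` for every bait. That is a
property of the scoring rules, not of the simulator.

**RIP-seq** (`simulateRip`): baseline relative expression is log-normal
across transcripts (sd 1 on the log scale); counts are negative-binomial
with dispersion `nb_dispersion` (default 0.05, a biological-replicate
scale BCV of ~0.22; 0 gives Poisson). Spiked transcripts have IP expected
counts exactly `enrichment_fold` (default 8) times their control expected
counts. `library_sizes` (default $2\times10^6$) is the expected *control*
total; spiking necessarily adds reads on top of that baseline in IP
samples, so IP totals exceed the target in proportion to the spiked mass —
the alternative (renormalizing IP columns) would silently shrink the
spiked fold and distort the ground truth. A side effect faithful to real
IP data is compositional: unspiked transcripts occupy a smaller fraction
of the IP library, so their TPM log-ratios centre slightly below zero.
Defaults: 2000 transcripts, 100 spiked, triplicates, lengths uniform in
500–5000 nt.

Both simulators draw from a single local RNG stream seeded per call and
restore the caller's RNG state. What the generator does **not** emulate:
peptide-to-protein inference, intensity-dependent dropout, batch or
run-order effects, read sequences, mappability, UV-crosslinking
efficiency, or transcript-specific dispersion. Passing recovery tests
therefore demonstrate that the scoring chain is correct under its own
model assumptions — not that those assumptions hold for any particular
real dataset.

# Numerical and design choices

* `Inf`/`NaN` arithmetic uses IEEE semantics throughout; `Inf` is written
  as the literal `Inf` in TSV outputs and `NaN` rows are dropped from
  result files with a logged count.
* Reporting thresholds are inclusive (≥ 2-fold, ≥ 50 reads, ≥ 50 RPKM,
  q ≤ 0.01); tier bounds are strict (> 1.5, > 4, > 8, intensity > floor).
* A sample with zero total intensity cannot be normalized and is a named
  error; an all-zero sample has no defined TPM and is likewise a named
  error; fewer than two replicates per group make the variance
  inestimable and are an error.
* Degenerate test inputs (both groups all zero) give statistic 0 and
  p = 1; groups with zero variance but differing proportions give an
  infinite statistic and p = 0.
* The test suite runs the calibration and recovery checks at the default
  study scale (2000 proteins / 2000 transcripts, triplicates) — large
  enough for stable Monte-Carlo summaries, small enough to run in
  seconds — with fixed seeds throughout.

# Worked example

```{r example, eval = FALSE}
sim <- simulateIpms(IpmsSimConfig(seed = 1))
enr <- ipmsEnrichment(sim$experiment)
head(subset(enr, reported))
sets <- baitSets(enr)
exclusivity(sets)

rip <- simulateRip(RipSimConfig(seed = 1))
tab <- ripEnrichment(rip$experiment)
table(truth = rip$truth$label, called = tab$passes_solid)
```

# Known limitations

* Ratio-only scoring has no variance model at the protein level (no
  SAINT/limma-style inference); confidence in a call rests on the peptide
  filter and the fold tiers, as in the motivating analyses.
* The pooled dispersion assumes a common squared-CV across transcripts;
  strongly transcript-specific dispersion would call for trended or
  shrunken estimates instead.
* The category rules are pattern matching over free-text descriptions; a
  true GO-DAG classification is out of scope.
* The `Inf` convention makes rare all-dropout control patterns look
  maximally enriched; with deeper designs (more replicates) this risk
  shrinks geometrically.
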