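---
title: "Methods: lncRNA discovery, classification and dosage-effect analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery, classification and dosage-effect analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncdosage)
```

## Scope and model of the data

`lncdosage` implements the downstream computational analysis of a bulk
RNA-seq comparison between *Drosophila* ISWI chromatin-remodeler mutants
and wild type, in both sexes: novel lncRNA discovery from assembled
transcript models, strand-aware positional classification of lncRNAs,
log2(mutant/WT) ratio distributions interpreted in a genomic-balance
dosage framework, a transparent differential-expression stage with
sex-concordance logic, lncRNA–mRNA co-expression screening, transposable
element (TE) family summaries, and embryo fluorescence quantification.
Upstream read processing (QC, alignment, transcript assembly) is outside
the package: inputs are an annotation (GTF), assembled transcript models
(GTF), a transcript × sample count matrix with a sample sheet, optional
external hit tables, a TE family map, and per-embryo channel intensities.

The experimental design the package assumes — and the synthetic generator
emulates — is 2 genotypes × 2 sexes × 3 replicates.

## Discovery: the filter-and-prediction chain

Candidate transcripts pass three pure per-transcript predicates, so stage
order cannot change the surviving set:

1. **Structural**: kept iff exon count ≥ 2 and length ≥ 200 nt (both
   inclusive). Single-exon models are overwhelmingly assembly artifacts,
   and 200 nt is the defining lower bound of the lncRNA class.
2. **Coding potential**: externally computed coding-potential hit tables
   are used when supplied. Otherwise a naive longest-ORF rule runs:
   *coding* iff the longest forward-strand ATG→stop ORF of the mature
   sequence reaches 100 codons or covers more than 35% of the transcript.
   This rule is deliberately simple and transparent — it is not a
   reimplementation of SVM-based coding-potential classifiers, and on real
   sequence it is a coarser instrument; its role is to let the chain run
   hermetically and be tested exactly against a brute-force ORF scan.
3. **Homology**: a candidate is discarded iff any hit from any supplied
   source (Pfam-type domain scans, NR/UniRef90-type protein searches) has
   E-value strictly below 1e-5. The inequality is strict: a hit at exactly
   1e-5 survives.

Noncoding survivors become novel lncRNA candidates; transcripts called
coding become novel mRNA candidates; transcripts already present in the
reference annotation bypass the chain and keep their reference biotype.
Every input transcript receives exactly one fate in the audit trail, and
the partition identity |input| = |kept| + Σ removed-by-reason is asserted
in the tests.

## Positional classification

Four classes, defined against protein-coding gene models only:

* **sense** — some exon of the lncRNA overlaps some exon of a gene on the
  same strand;
* **antisense** — the lncRNA span overlaps a gene span on the opposite
  strand;
* **intronic** — the lncRNA lies within a gene's intronic sequence with no
  exonic overlap (canonically: fully contained in a single intron);
* **lincRNA** — the lncRNA span overlaps no protein-coding gene span.

When a transcript relates to several genes in different ways the label is
decided by precedence sense > antisense > intronic > lincRNA: exonic
same-strand overlap is the strongest (and most consequential for
quantification) relation, and any opposite-strand overlap outranks mere
intron residency. This precedence is a design decision of this package;
the class names themselves do not dictate a tie-break.

One geometry falls outside the four textbook definitions: a spliced
transcript can overlap a gene on the same strand through intronic sequence
only, without being contained in any single intron (e.g. straddling the
gene boundary, or bridging two introns around an exon it does not touch).
We label this case **intronic** with evidence kind `intron_overlap`,
reserving `intron_containment` for the canonical case. The alternative —
letting it fall through to lincRNA — would break the invariant that a
lincRNA call guarantees zero gene-span overlap, which downstream
interpretation (and our property tests) rely on. A same-strand-only
restriction for the intronic class would be vacuous here: under the
precedence above, every opposite-strand candidate is already antisense
before the intronic rule is reached.

The implementation uses `GenomicRanges` overlap machinery; the test suite
re-derives every label with an independent brute-force enumeration of all
(gene, overlap-kind) pairs on randomly generated annotations, and the two
must agree exactly.

## Normalization and the dosage framework

Counts are normalized by **median-of-ratios** size factors: the
pseudo-reference is the per-transcript geometric mean over samples
(restricted to transcripts with no zero count), and a sample's factor is
the median of count/reference over those transcripts. `baseMean` is the
mean of normalized counts across all samples — by default all 12, because
the TE expression filter (`baseMean > 500`, strict) is defined on the full
panel; a per-sex baseMean can be formed by subsetting the matrix first.

For one sex, the per-transcript ratio is
log2(mean of mutant replicates / mean of WT replicates) on normalized
counts. Transcripts whose two group means do not both reach the expression
floor (1 normalized count by default) are excluded rather than set to NA
or rescued with a pseudocount: exclusion keeps every retained ratio finite
and unbiased, at the cost of silence about the lowest-expression stratum,
which a ratio cannot estimate stably anyway.

Ratio distributions are read against three reference lines: 0 (dosage
compensation, ratio 1), +log2(3/2) ≈ 0.58 (positive dosage effect) and
−log2(3/2) (inverse dosage effect) — the changes expected when a 2:3
genomic imbalance propagates directly or inversely to a target.
Histograms use 0.1-wide, left-closed bins over [−3, 3); frequencies are
relative to all records of the class, so in-range frequencies sum to the
in-range fraction and out-of-range mass is reported separately. Stratified
medians are reported per (X/autosome stratum × class), optionally after
restriction to an id subset (e.g. X-linked transcription factors). The
distribution comparison behind the mRNA-vs-lncRNA panels is a two-sample
Kolmogorov–Smirnov test (asymptotic p); the choice of test is a documented
stand-in, since such panels are conventionally annotated with an unnamed
two-sample p-value.

**A caveat the synthetic experiments make visible:** median-of-ratios
assumes most transcripts are unchanged. When a planted shift affects a
noticeable, one-sided fraction of the transcriptome, the mutant samples'
size factors absorb part of it and every ratio drifts by a few hundredths
of a log2 unit (≈0.05–0.1 at 13–19% contamination under our noise
levels). The package does not correct this — neither do the standard
tools — but the stratified-median table makes the drift visible as a
nonzero mRNA median, and the contrast "class median − mRNA median" is the
drift-robust readout.

## Differential expression

The DE stage is a deliberately transparent negative-binomial Wald test,
not a reimplementation of shrinkage-based frameworks: per-sex size
factors; per-transcript moment dispersion
α = (s² − μ)/μ² pooled across the two groups and floored at 1e-8;
log2 fold change from the normalized group means; delta-method standard
error under the NB variance model; two-sided normal p; Benjamini–Hochberg
adjustment over the tested transcripts. Calls use padj < 0.05 with no
fold-change cutoff. Transcripts with all-zero counts are excluded before
testing; a group mean of zero with a non-zero counterpart is floored at
0.5 normalized counts so the statistic stays finite. Externally computed
DE tables with the same schema can be ingested in place of this stage.

Null simulations (no planted effect, NB dispersion 0.05) keep the
padj < 0.05 call rate near 3%, and planted 4-fold effects at mean ≥ 100
with 3 replicates are recalled essentially completely — both are asserted
in the acceptance tests at 2000 transcripts × 50 seeds and 200 planted
effects respectively.

Sex concordance intersects the per-sex up/down sets: Venn-style counts
(female-only, male-only, both) per direction, and the four trend
categories (both up, both down, up-in-F/down-in-M, down-in-F/up-in-M)
partitioning the both-sex DE intersection.

## Co-expression screening

All lncRNA × mRNA pairs are tested by Pearson correlation across the
shared samples (all 12 by default — the sample basis is a documented
choice; a per-sex screen is a matter of subsetting the matrices).
P-values come from t = r√((n−2)/(1−r²)) on n−2 df. An edge is kept iff
|r| > 0.95 and p < 0.05 (both strict). The absolute-value form is the
default because negative edges are biologically meaningful and standard in
co-expression networks; a signed mode (`r > r_min`) is available. No
multiple-testing correction is applied to pair p-values — the screen is a
candidate generator, not an inference. Connection degrees rank nodes
descending with an alphabetical tie-break.

## TE families

A TE instance passes iff it is DE (call ≠ ns) and baseMean > 500
(strict). Families are summarized by count of passing instances,
proportion of the *annotated* family size (the denominator choice is
documented — the expressed family size is an alternative), and mean
baseMean of passing instances ("expression level" at family scale; a
max-aggregation would emphasize single outlier insertions). Three
independent descending rankings (count, proportion, mean baseMean) with
alphabetical tie-breaks feed a consensus flag for families in all three
top-10 lists. Family membership comes from an explicit instance→family
table, never from parsing instance names.

## Embryo fluorescence quantification

Each embryo contributes one relative intensity: probe-channel mean over
DAPI-channel mean, which cancels exposure and embryo-size effects (the
ratio is invariant to scaling both channels). Genotypes are compared per
stage group (St1-5, St6-11, St12-17) by the pooled-variance Student
t-test — pooled rather than Welch because group sizes and acquisition
settings are matched in this design; Welch is available by flag. Labels
follow the conventional mapping NS. (p ≥ 0.05), * (< 0.05), ** (< 0.01),
*** (< 0.001). The degenerate all-equal case returns NS. with a warning
instead of NaN. Image segmentation is out of scope: the module consumes
per-embryo channel summaries as produced by standard image tooling.

## The synthetic generator: what it emulates, and what it does not

`sim_config()` fixes the study conditions; every draw flows from one
seed, and derived stages use fixed offsets from it, so a config is a
complete, reproducible description of a dataset.

* **Annotation**: genes (2–5 exons, 200–600 nt exons, 0.8–2 kb introns)
  and lncRNAs placed so each class definition holds *by construction* —
  lincRNAs in intergenic gaps, intronic lncRNAs inside a host intron on
  the host strand, sense lncRNAs with a guaranteed exon overlap, antisense
  lncRNAs opposite-strand within a host gene. Default 80 genes per arm:
  enough unchanged mRNA background that median-of-ratios normalization
  operates in its intended regime (see the caveat above). The default
  lncRNA mixture (584/254/95/67) realizes class proportions of
  58.4/25.4/9.5/6.7%.
* **Counts**: negative binomial with dispersion 0.05 (a typical
  well-replicated bulk value; 0 degenerates to Poisson), per-transcript
  log-normal baseline means (median 150), per-sample library factors
  log-uniform in [0.7, 1.4] so size-factor estimation is non-trivial.
  Planted effects are multiplicative in the mutant: a +1.0 log2 shift on
  X-chromosome lncRNAs in males (the dosage signature under study),
  per-class autosomal shifts (+0.4 lincRNA, −0.2 intronic by default),
  4-fold DE mRNAs in eight sex-pattern categories, and TE families up- or
  down-regulated at high baseline expression.
* **Co-expressed pairs** share a per-sample latent factor (log2 SD 0.9,
  chosen so the realized pair correlation on the normalized-count scale
  is ≈0.98) at high mean and low dispersion, among independent decoys.
* **Sequences** are generated stop-dense (a stop cassette covering all
  three frames every ~45 nt) for noncoding transcripts and with a planted
  ≥100-codon ORF for coding decoys, so the naive coding rule's ground
  truth is unambiguous. Random uniform sequence would not do: short
  transcripts frequently contain chance ORFs above the 35% coverage rule,
  which is a property of the rule worth knowing about on real data.
* **Embryos**: normal probe and DAPI intensities per (genotype, stage),
  defaults emulating a progressive mutant decline (95/75/55 vs 100)
  against DAPI 50 ± 5 with 8 embryos per group.

What the generator does **not** emulate: isoform-level quantification
ambiguity, GC/length biases, batch effects, outlier samples,
overdispersion heterogeneity, or genuine sequence composition. Passing
tests therefore demonstrate that the *algorithms* recover planted
structure under the stated noise model — not that the defaults capture
every failure mode of real libraries.

### Problem sizes used in the validation runs

The classifier–oracle comparison uses 1000 random annotations (300 in the
acceptance script); generator cross-validation runs the full default
config (1000 lncRNAs over 480 genes); size-factor and DE calibration use
2000 transcripts (50 seeds for the null rate); the dosage-shift recovery
uses 500 X-linked lincRNAs against 2400 anchoring mRNAs; co-expression
recovery uses 20 planted pairs among 200 decoys. These sizes give the
recovery statistics comfortable margins under the stated noise model
while keeping a full validation run in the low minutes on one core.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GTF convention);
  conversion helpers to half-open and back are exact inverses.
* All tabular outputs are written deterministically (schema column order,
  primary-key row order, fixed float precision), so reruns are
  byte-identical and outputs diff cleanly.
* `size_factors()` errors when no transcript is positive in all samples
  rather than silently switching reference — sparse single-cell-like
  matrices need a different estimator by explicit choice.
* Ties in rankings break alphabetically; bins are left-closed; length
  bins treat internal upper edges as inclusive (<1000, 1000–3000, >3000).
* Empty groups are omitted with warnings, not fabricated; undefined
  correlations (constant vectors) and sub-minimal group sizes are errors.

## Known limitations

The naive ORF rule is a coarse stand-in for dedicated coding-potential
classifiers; on real transcripts, supply external hit tables. The DE
stage has no dispersion shrinkage, so it is conservative at very low
counts and should not be expected to match shrinkage-based tools
call-for-call. The dosage analysis reports medians of ratio
distributions; it does not model the compensation mechanism itself. The
co-expression screen is correlation-only: no direction, no causality, no
correction for shared genotype structure — planted DE transcripts of the
same sign will legitimately correlate across a 12-sample panel, which is
visible in the demo pipeline's edge list.
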