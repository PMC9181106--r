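# lncdosage

Downstream transcriptomic analysis for *Drosophila* ISWI
chromatin-remodeler mutant vs wild-type RNA-seq, with a focus on long
noncoding RNAs (lncRNAs) and genomic-balance dosage effects. The package
is for computational biologists who have assembled transcript models and
a transcript × sample count matrix (2 genotypes × 2 sexes × replicates)
and want a tested, reproducible implementation of the downstream chain:

* **Discovery** — novel lncRNA / novel mRNA candidates from assembled
  transcripts via structural (exon ≥ 2, length ≥ 200 nt), coding-potential
  and homology (E < 1e-5, strict) filters, with a complete per-transcript
  audit trail.
* **Classification** — strand-aware positional classes
  (lincRNA / intronic / sense / antisense) against protein-coding gene
  models, precedence sense > antisense > intronic > lincRNA.
* **Dosage analysis** — median-of-ratios normalization, per-transcript
  log2(mutant/WT) ratios with an expression floor, histograms and
  stratified medians framed by the reference lines 0 (compensation) and
  ±log2(3/2) ≈ ±0.58 (positive / inverse dosage effect).
* **Differential expression** — a transparent negative-binomial Wald test
  (moment dispersion, BH adjustment, padj < 0.05) plus sex-concordance
  sets (both-up, both-down, and the two discordant categories).
* **Co-expression** — all lncRNA × mRNA Pearson screening at |r| > 0.95,
  p < 0.05, with connection-degree ranking.
* **TE analysis** — DE transposable-element instances filtered at
  baseMean > 500 (strict), family counts/proportions/expression, top-10
  rankings on three criteria.
* **FISH quantification** — per-embryo probe/DAPI intensity ratios,
  pooled Student t per stage group (St1-5, St6-11, St12-17), star labels.
* **Synthetic data** — a generator that plants all of the above
  (dosage shifts, DE patterns, co-expressed pairs, TE families, decoys)
  with recoverable truth, used throughout the test suite.

The core quantity is the per-transcript expression ratio
`log2(mean_ISWI / mean_WT)` on normalized counts, read against the
genomic-balance frame: a ratio of 1 (log2 = 0) marks dosage compensation,
3/2 (log2 ≈ 0.58) a positive dosage effect, 2/3 an inverse dosage effect.
Normalization uses the median-of-ratios estimator: for sample *j*,
`sf_j = median_i ( c_ij / (prod_j c_ij)^(1/n) )` over transcripts with no
zero count.

## Worked example

Everything runs end-to-end on synthetic data from one seeded config:

```r
library(lncdosage)
res <- run_pipeline(sim_config(seed = 1), out_dir = "demo_out")

res$proportions
#> # A tibble: 4 × 4
#>   class         n fraction percent
#>   <chr>     <int>    <dbl>   <dbl>
#> 1 lincRNA     584    0.584    58.4
#> 2 intronic    254    0.254    25.4
#> 3 sense        95    0.095     9.5
#> 4 antisense    67    0.067     6.7

res$discovery
#> <discovery_result> 1000 novel lncRNA, 5 novel mRNA, 0 known, 15 removed
#>   removed by: homology=5, structural_exon=5, structural_length=5
```

The generator planted 1000 valid lncRNAs (584/254/95/67 across the four
classes) plus 15 decoys; discovery removes exactly the decoys, and every
survivor is classified back to its planted class — the proportions table
is the generator's mixture recovered exactly.

```r
m <- res$medians$M
m[m$class %in% c("lincRNA", "mRNA"), ]
#> # A tibble: 4 × 4
#>   stratum  class       n median_log2_ratio
#>   <chr>    <chr>   <int>             <dbl>
#> 1 X        lincRNA    97             0.825
#> 2 X        mRNA       80            -0.295
#> 3 autosome lincRNA   487             0.186
#> 4 autosome mRNA      400            -0.193
```

Male X-linked lincRNAs carry the planted +1.0 log2 dosage shift: their
median sits far above the mRNA background (the small negative mRNA median
is the normalization drift a heavily shifted transcriptome induces — see
the methods vignette; the class-minus-mRNA contrast, 0.825 − (−0.295) ≈
1.1, is the drift-robust readout).

```r
res$concordance
#> <concordance_sets> 155 transcript(s) DE in both sexes
#>   both_up: 71
#>   both_down: 70
#>   F_up_M_down: 6
#>   F_down_M_up: 8

res$fish
#> # A tibble: 3 × 8
#>   stage    n_wt n_mut mean_wt mean_mut      t          p label
#> 1 St1-5       8     8    1.84     1.85  0.114 0.911      NS.
#> 2 St6-11      8     8    2.12     1.32 -7.41  0.00000328 ***
#> 3 St12-17     8     8    1.85     1.11 -7.68  0.00000219 ***
```

The embryo table was generated with equal group means at St1-5 and a
progressive mutant decline afterwards; the pooled t-test reports exactly
that pattern. `plot_ratio_distribution()`, `plot_class_proportions()` and
`plot_fish_comparison()` give ggplot views of the corresponding tables,
and `out_dir` receives one deterministic TSV per stage plus a JSON run
manifest (reruns are byte-identical).

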