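Package: lncdosage
Title: lncRNA Discovery, Positional Classification and Dosage-Effect
    Expression Analysis for Chromatin-Remodeler Mutant RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for the transcriptomic analysis of
    chromatin-remodeler (ISWI) mutant versus wild-type Drosophila RNA-seq:
    novel long noncoding RNA (lncRNA) discovery by structural, coding-potential
    and homology filtering; strand-aware positional classification of lncRNAs
    into lincRNA, intronic, sense and antisense classes; median-of-ratios
    count normalization and log2 mutant/wild-type ratio distributions framed
    by genomic-balance dosage reference lines; a transparent negative-binomial
    Wald differential-expression stage with sex-concordance set logic;
    lncRNA-mRNA co-expression screening by Pearson correlation; transposable
    element family summaries; and embryo fluorescence-ratio quantification.
    A synthetic-data generator with planted, recoverable effects supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
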