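toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"), chromosome = "2L", strand = c("+", "-"),
    start = c(5000L, 20000L), end = c(8000L, 24000L),
    biotype = "protein_coding")
}

toy_reference <- function() {
  make_annotation(
    toy_genes(),
    list(
      list(id = "tA", gene = "gA", chrom = "2L", strand = "+",
           biotype = "protein_coding",
           exons = list(c(5000, 5200), c(7800, 8000))),
      list(id = "tB", gene = "gB", chrom = "2L", strand = "-",
           biotype = "protein_coding",
           exons = list(c(20000, 20500), c(23500, 24000)))
    ))
}

classify_one <- function(exons, strand) {
  ref <- toy_reference()
  ann <- genome_annotation(
    ref$genes,
    dplyr::bind_rows(
      dplyr::select(ref$transcripts, "transcript_id", "gene_id",
                    "chromosome", "strand", "biotype"),
      tibble::tibble(transcript_id = "lnc", gene_id = NA_character_,
                     chromosome = "2L", strand = strand,
                     biotype = "lncRNA")),
    dplyr::bind_rows(ref$exons,
                     tibble::tibble(transcript_id = "lnc",
                                    start = sapply(exons, `[`, 1),
                                    end = sapply(exons, `[`, 2))))
  classify_lncrnas("lnc", ann)
}

test_that("the four canonical geometries get their class", {
  # far from both genes: lincRNA
  r <- classify_one(list(c(1000, 1500), c(1700, 2000)), "+")
  expect_equal(r$class, "lincRNA")
  expect_equal(r$evidence_kind, "none")
  expect_true(is.na(r$evidence_gene))
  # fully inside gA's intron (5201..7799), same strand, no exon overlap
  r <- classify_one(list(c(5300, 5400), c(6000, 6200)), "+")
  expect_equal(r$class, "intronic")
  expect_equal(r$evidence_kind, "intron_containment")
  expect_equal(r$evidence_gene, "gA")
  # exon-exon overlap with gA on the same strand: sense
  r <- classify_one(list(c(5100, 5250), c(6000, 6100)), "+")
  expect_equal(r$class, "sense")
  expect_equal(r$evidence_kind, "exonic_same_strand")
  # inside gB's span on the opposite strand (gB is "-"): antisense
  r <- classify_one(list(c(21000, 21200), c(22000, 22200)), "+")
  expect_equal(r$class, "antisense")
  expect_equal(r$evidence_kind, "opposite_strand")
})

test_that("sense wins over antisense when both relations exist", {
  # one exon overlapping gA's first exon (same strand), another inside
  # gB's intron (opposite strand): precedence says sense
  r <- classify_one(list(c(5100, 5250), c(21000, 21300)), "+")
  expect_equal(r$class, "sense")
  expect_equal(r$evidence_gene, "gA")
})

test_that("classification matches the exhaustive-overlap oracle on random annotations", {
  set.seed(1234)
  for (i in 1:300) {
    ann <- random_annotation()
    got <- classify_lncrnas("lnc", ann)
    expect_equal(got$class, oracle_classify("lnc", ann), info = i)
  }
})

test_that("labels are invariant under a global strand flip", {
  set.seed(77)
  flip <- function(s) ifelse(s == "+", "-", "+")
  for (i in 1:40) {
    ann <- random_annotation()
    flipped <- genome_annotation(
      dplyr::mutate(ann$genes, strand = flip(.data$strand)),
      dplyr::mutate(
        dplyr::select(ann$transcripts, "transcript_id", "gene_id",
                      "chromosome", "strand", "biotype"),
        strand = flip(.data$strand)),
      ann$exons)
    expect_equal(classify_lncrnas("lnc", flipped)$class,
                 classify_lncrnas("lnc", ann)$class, info = i)
  }
})

test_that("a lincRNA call guarantees zero overlap with every gene span", {
  set.seed(555)
  for (i in 1:150) {
    ann <- random_annotation()
    got <- classify_lncrnas("lnc", ann)
    if (got$class != "lincRNA") next
    tex <- ann$exons[ann$exons$transcript_id == "lnc", ]
    span <- c(min(tex$start), max(tex$end))
    g <- ann$genes
    expect_false(any(span[1] <= g$end & g$start <= span[2]), info = i)
  }
})

test_that("an unknown chromosome is an error", {
  ann <- toy_reference()
  bad <- genome_annotation(
    ann$genes,
    dplyr::bind_rows(
      dplyr::select(ann$transcripts, "transcript_id", "gene_id",
                    "chromosome", "strand", "biotype"),
      tibble::tibble(transcript_id = "lnc", gene_id = NA_character_,
                     chromosome = "chrU", strand = "+", biotype = "lncRNA")),
    dplyr::bind_rows(ann$exons,
                     tibble::tibble(transcript_id = "lnc", start = 1L,
                                    end = 300L)))
  lnc_only <- genome_annotation(
    bad$genes[0, ],
    bad$transcripts[bad$transcripts$transcript_id == "lnc",
                    c("transcript_id", "gene_id", "chromosome", "strand",
                      "biotype")],
    bad$exons[bad$exons$transcript_id == "lnc", ])
  expect_error(classify_lncrnas(lnc_only, toy_reference()), "chrU")
})

test_that("class proportions sum to one and handle degenerate inputs", {
  p <- class_proportions(c("lincRNA", "lincRNA", "intronic", "sense"))
  expect_equal(p$fraction, c(0.5, 0.25, 0.25, 0))
  expect_lt(abs(sum(p$fraction) - 1), 1e-12)
  p1 <- class_proportions(rep("antisense", 5))
  expect_equal(p1$fraction[p1$class == "antisense"], 1)
  expect_equal(sum(p1$n), 5)
  expect_error(class_proportions(character()), "no labels")
  expect_error(class_proportions("mystery"), "unknown class")
})

test_that("structural summaries bin and conserve transcript counts", {
  tx <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    biotype = c("lncRNA", "lncRNA", "protein_coding", "protein_coding"),
    exon_count = c(2L, 7L, 3L, 1L),
    length = c(250L, 3000L, 5000L, 800L),
    chromosome = c("2L", "X", "3R", "scaffold_1"))
  s <- summarize_structure(tx)
  one <- s$structure[s$structure$biotype == "lncRNA" &
                       s$structure$exon_bin == "2", ]
  expect_equal(one$length_bin, "<1000")
  expect_equal(one$n, 1)
  # exon counts >= 5 pool; length 3000 stays in the middle bin
  seven <- s$structure[s$structure$exon_bin == ">=5", ]
  expect_equal(seven$length_bin, "1000-3000")
  # totals conserve per biotype
  tot <- tapply(s$structure$n, s$structure$biotype, sum)
  expect_equal(as.integer(tot[c("lncRNA", "protein_coding")]), c(2L, 2L))
  # non-arm chromosome grouped as other
  expect_equal(s$chromosome$arm[s$chromosome$biotype == "protein_coding"],
               c("3R", "other"))
})
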