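gtf_line <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

write_toy_gtf <- function(path) {
  writeLines(c(
    gtf_line("2L", "transcript", 101, 1000, "+",
             'gene_id "g1"; transcript_id "tx1"; gene_biotype "protein_coding";'),
    gtf_line("2L", "exon", 900, 1000, "+",
             'gene_id "g1"; transcript_id "tx1";'),
    gtf_line("2L", "exon", 101, 200, "+",
             'gene_id "g1"; transcript_id "tx1";'),
    gtf_line("X", "transcript", 50, 400, "-",
             'gene_id "g2"; transcript_id "tx2"; gene_biotype "lncRNA";'),
    gtf_line("X", "exon", 50, 400, "-",
             'gene_id "g2"; transcript_id "tx2";'),
    gtf_line("X", "CDS", 60, 300, "-",
             'gene_id "g2"; transcript_id "tx2";')
  ), path)
  path
}

test_that("GTF reading preserves 1-based inclusive coordinates and sorts exons", {
  path <- write_toy_gtf(withr::local_tempfile(fileext = ".gtf"))
  ann <- suppressMessages(read_annotation(path))
  tx1 <- ann$transcripts[ann$transcripts$transcript_id == "tx1", ]
  # exon 101-200 has length 100 (end - start + 1); out-of-order exons sorted
  ex1 <- ann$exons[ann$exons$transcript_id == "tx1", ]
  expect_equal(ex1$start, c(101, 900))
  expect_equal(ex1$end[1] - ex1$start[1] + 1, 100)
  expect_equal(tx1$length, 100 + 101)
  expect_equal(tx1$exon_count, 2)
  expect_equal(tx1$biotype, "protein_coding")
  tx2 <- ann$transcripts[ann$transcripts$transcript_id == "tx2", ]
  expect_equal(tx2$strand, "-")
  expect_equal(tx2$biotype, "lncRNA")
})

test_that("a GTF with no transcript records yields an empty annotation with a warning", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_line("2L", "gene", 1, 10, "+", 'gene_id "g1";'), path)
  expect_warning(ann <- read_annotation(path), "empty annotation")
  expect_equal(nrow(ann$transcripts), 0)
})

test_that("exon records missing transcript_id are a parse error", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_line("2L", "exon", 1, 10, "+", 'gene_id "g1";'), path)
  expect_error(read_annotation(path), "transcript_id")
})

test_that("annotation round-trips through GTF exactly", {
  set.seed(4)
  gen <- generate_annotation(quick_config(seed = 4))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(gen$annotation, path)
  back <- suppressMessages(read_annotation(path))
  a <- gen$annotation
  expect_equal(back$exons, a$exons)
  cols <- c("transcript_id", "chromosome", "strand", "exon_count", "length")
  expect_equal(as.data.frame(back$transcripts[, cols]),
               as.data.frame(a$transcripts[, cols]))
})

test_that("half-open conversion is the identity when round-tripped", {
  ex <- tibble::tibble(transcript_id = "t", start = c(101L, 900L),
                       end = c(200L, 1000L))
  expect_equal(exons_to_one_based(exons_to_half_open(ex)), ex)
  # 1-based inclusive exon 101-200 becomes half-open [100, 200): width 100
  ho <- exons_to_half_open(ex)
  expect_equal(ho$end[1] - ho$start[1], 100)
})

test_that("count matrix reading validates the integer contract", {
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "counts.tsv")
  spath <- file.path(dir, "sheet.tsv")
  writeLines(c("transcript_id\ts1\ts2", "txA\t1\t2", "txB\t3\t4"), cpath)
  writeLines(c("sample_id\tgenotype\tsex\treplicate",
               "s2\tISWI\tF\t1", "s1\tWT\tF\t1"), spath)
  cm <- read_counts(cpath, spath)
  # column order follows the sheet
  expect_equal(colnames(cm$counts), c("s2", "s1"))
  expect_equal(unname(cm$counts["txA", "s2"]), 2L)

  writeLines(c("transcript_id\ts1\ts2", "txA\t3.5\t2", "txB\t3\t4"), cpath)
  expect_error(read_counts(cpath, spath), "integer")

  writeLines(c("transcript_id\ts1\ts2", "txA\t1\t2", "txA\t3\t4"), cpath)
  expect_error(read_counts(cpath, spath), "txA")

  writeLines(c("transcript_id\ts1", "txA\t1"), cpath)
  expect_error(read_counts(cpath, spath), "missing")
})

test_that("hit tables are read verbatim and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx1\t1e-6", "tx2\t0.2"), path)
  h <- read_hits(path, "pfam")
  expect_equal(h$e_value, c(1e-6, 0.2))
  expect_equal(unique(h$source), "pfam")

  writeLines(character(), path)
  expect_equal(nrow(read_hits(path, "nr")), 0)

  writeLines("tx1\t-1", path)
  expect_error(read_hits(path, "pfam"), "non-negative")
})

test_that("write_table is deterministic and schema-checked", {
  edges <- tibble::tibble(lncRNA_id = c("b", "a"), mRNA_id = c("m1", "m2"),
                          r = c(0.99, -0.97), p = c(1e-4, 2e-3),
                          sign = c("positive", "negative"))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_table(edges, p1, "edges")
  write_table(edges[2:1, ], p2, "edges")  # row order must not matter
  expect_identical(readLines(p1), readLines(p2))
  out <- readLines(p1)
  expect_equal(out[1], "lncRNA_id\tmRNA_id\tr\tp\tsign")
  expect_equal(length(out), 3)

  write_table(edges[0, ], p1, "edges")
  expect_equal(readLines(p1), "lncRNA_id\tmRNA_id\tr\tp\tsign")

  expect_error(write_table(edges[, -3], p1, "edges"), "missing field")
  expect_error(write_table(edges, p1, "nope"), "unknown schema")
})

test_that("annotation containers enforce their structural invariants", {
  genes <- tibble::tibble(gene_id = "g", chromosome = "2L", strand = "+",
                          start = 1L, end = 1000L,
                          biotype = "protein_coding")
  tx <- tibble::tibble(transcript_id = "t", gene_id = "g",
                       chromosome = "2L", strand = "+",
                       biotype = "protein_coding")
  expect_error(genome_annotation(
    genes, tx, tibble::tibble(transcript_id = "t", start = 10L, end = 5L)),
    "end < start")
  expect_error(genome_annotation(
    genes, tx, tibble::tibble(transcript_id = "t", start = c(1L, 50L),
                              end = c(100L, 120L))),
    "overlapping")
  expect_error(genome_annotation(
    genes, tx, tibble::tibble(transcript_id = "t", start = 900L,
                              end = 1100L)),
    "outside the gene span")
})
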