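test_that("structural filter applies its inclusive thresholds", {
  tx <- tibble::tibble(
    transcript_id = c("single", "short", "boundary", "good"),
    exon_count = c(1L, 2L, 2L, 3L),
    length = c(500L, 199L, 200L, 1000L))
  res <- structural_filter(tx)
  expect_equal(res$kept, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$reason[1:2], c("structural_exon", "structural_length"))
  expect_true(all(is.na(res$reason[3:4])))
  # empty in, empty out
  expect_equal(nrow(structural_filter(tx[0, ])), 0)
})

test_that("longest ORF matches a brute-force start/stop scan", {
  expect_equal(longest_orf("CCCCCCCCCCCC"), 0L)          # no ATG
  expect_equal(longest_orf("ATGAAATAA"), 9L)             # ATG AAA TAA
  expect_equal(longest_orf("GATGAAATAA"), 9L)            # frame 1
  expect_error(longest_orf(""), "non-empty")
  set.seed(99)
  for (i in 1:60) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    expect_equal(longest_orf(s), oracle_longest_orf(s), info = i)
  }
})

test_that("the naive coding rule fires at its stated thresholds", {
  sense <- c("GCT", "GGA", "CTT", "AGA")  # stop-free codons
  orf150 <- paste0("ATG", paste(rep(sense, length.out = 149), collapse = ""),
                   "TAA")
  pad <- paste(rep("C", 2000 - nchar(orf150)), collapse = "")
  v <- naive_coding_filter(c(tx = paste0(orf150, pad)))
  expect_equal(v$verdict, "coding")      # ORF >= 100 codons
  expect_gte(v$orf_codons, 100)

  # short ORF but high coverage: 40 codons in a 300 nt transcript (40%)
  orf40 <- paste0("ATG", paste(rep(sense, length.out = 38), collapse = ""),
                  "TAA")
  pad2 <- paste(rep("C", 300 - nchar(orf40)), collapse = "")
  v2 <- naive_coding_filter(c(tx = paste0(orf40, pad2)))
  expect_equal(v2$verdict, "coding")     # coverage 120/300 = 0.4 > 0.35
  # same ORF diluted below the coverage rule
  pad3 <- paste(rep("C", 500 - nchar(orf40)), collapse = "")
  v3 <- naive_coding_filter(c(tx = paste0(orf40, pad3)))
  expect_equal(v3$verdict, "noncoding")
})

test_that("homology filter removes only strictly significant hits", {
  hits <- tibble::tibble(transcript_id = c("a", "b", "c"),
                         e_value = c(1e-6, 1e-4, 1e-5),
                         source = "pfam")
  res <- homology_filter(c("a", "b", "c", "d"), hits)
  expect_equal(res$kept, c(FALSE, TRUE, TRUE, TRUE))  # strict < 1e-5
  # row order of the hit table is irrelevant
  res2 <- homology_filter(c("a", "b", "c", "d"), hits[3:1, ])
  expect_equal(res, res2)
})

test_that("run_discovery keeps exactly the planted lncRNAs with a complete audit", {
  cfg <- quick_config(seed = 61,
                      lnc_class_counts = c(lincRNA = 20, intronic = 0,
                                           sense = 0, antisense = 0),
                      decoy_counts = c(single_exon = 5, short = 3,
                                       coding = 3, homology = 4))
  sim <- simulate_discovery_input(cfg)
  res <- run_discovery(sim$assembled, sequences = sim$sequences,
                       hits = sim$hits, reference = sim$reference)
  expect_setequal(res$novel_lncRNA, sim$truth$planted_lnc)
  roles <- sim$truth$roles
  expect_setequal(res$novel_mRNA,
                  roles$transcript_id[roles$role == "decoy_coding"])
  # audit partition: every input transcript appears exactly once
  expect_setequal(res$audit$transcript_id,
                  sim$assembled$transcripts$transcript_id)
  expect_equal(nrow(res$audit),
               length(res$novel_lncRNA) + length(res$novel_mRNA) +
                 sum(!res$audit$fate %in% c("novel_lncRNA", "novel_mRNA",
                                            "known")))
  expect_equal(sum(res$audit$fate == "structural_exon"), 5)
  expect_equal(sum(res$audit$fate == "structural_length"), 3)
  expect_equal(sum(res$audit$fate == "homology"), 4)
  # hit-table row order does not change the result
  res2 <- run_discovery(sim$assembled, sequences = sim$sequences,
                        hits = sim$hits[sample(nrow(sim$hits)), ],
                        reference = sim$reference)
  expect_equal(res2$novel_lncRNA, res$novel_lncRNA)
  expect_equal(res2$audit, res$audit)
})

test_that("discovery handles the empty and error cases", {
  empty <- genome_annotation(
    tibble::tibble(gene_id = character(), chromosome = character(),
                   strand = character(), start = integer(), end = integer(),
                   biotype = character()),
    tibble::tibble(transcript_id = character(), gene_id = character(),
                   chromosome = character(), strand = character(),
                   biotype = character()),
    tibble::tibble(transcript_id = character(), start = integer(),
                   end = integer()))
  res <- run_discovery(empty)
  expect_length(res$novel_lncRNA, 0)
  expect_equal(nrow(res$audit), 0)

  cfg <- quick_config(seed = 62)
  sim <- simulate_discovery_input(cfg)
  expect_error(run_discovery(sim$assembled, sequences = sim$sequences[1:2],
                             hits = sim$hits),
               "sequence missing")
})

test_that("known reference transcripts bypass discovery", {
  cfg <- quick_config(seed = 63)
  sim <- simulate_discovery_input(cfg)
  # declare one candidate as already known
  known_id <- sim$assembled$transcripts$transcript_id[1]
  ref <- sim$reference
  ref_tx <- dplyr::bind_rows(
    dplyr::select(ref$transcripts, "transcript_id", "gene_id", "chromosome",
                  "strand", "biotype"),
    dplyr::mutate(sim$assembled$transcripts[1, c("transcript_id", "gene_id",
                                                 "chromosome", "strand",
                                                 "biotype")],
                  biotype = "lncRNA"))
  ref2 <- genome_annotation(
    ref$genes, ref_tx,
    dplyr::bind_rows(ref$exons,
                     sim$assembled$exons[
                       sim$assembled$exons$transcript_id == known_id, ]))
  res <- run_discovery(sim$assembled, sequences = sim$sequences,
                       hits = sim$hits, reference = ref2)
  expect_equal(res$known, known_id)
  expect_false(known_id %in% res$novel_lncRNA)
  expect_equal(res$audit$fate[res$audit$transcript_id == known_id], "known")
})

test_that("tidy() on a discovery result returns the audit trail", {
  cfg <- quick_config(seed = 64)
  sim <- simulate_discovery_input(cfg)
  res <- run_discovery(sim$assembled, sequences = sim$sequences,
                       hits = sim$hits)
  expect_identical(tidy(res), res$audit)
})
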