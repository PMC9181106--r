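# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's interval machinery: plain loops and
# arithmetic only.

# --- exhaustive-overlap positional classifier oracle -----------------------

# overlap of two 1-based inclusive intervals
.iv_overlap <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2

# classify one transcript by enumerating every (gene, overlap-kind) pair
# and applying the documented precedence:
# sense (same-strand exon-exon) > antisense (opposite-strand span overlap)
# > intronic (single-intron containment, then any same-strand span overlap)
# > lincRNA
oracle_classify <- function(tx_id, annotation) {
  tx <- annotation$transcripts[annotation$transcripts$transcript_id == tx_id, ]
  tex <- annotation$exons[annotation$exons$transcript_id == tx_id, ]
  span <- c(min(tex$start), max(tex$end))
  genes <- annotation$genes[annotation$genes$biotype == "protein_coding" &
                              annotation$genes$chromosome == tx$chromosome, ]
  has_sense <- FALSE; has_anti <- FALSE
  has_contain <- FALSE; has_same_span <- FALSE
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (!.iv_overlap(span[1], span[2], g$start, g$end)) next
    if (g$strand != tx$strand) {
      has_anti <- TRUE
      next
    }
    has_same_span <- TRUE
    # gene exon union = exons of all its transcripts
    g_tx <- annotation$transcripts$transcript_id[
      !is.na(annotation$transcripts$gene_id) &
        annotation$transcripts$gene_id == g$gene_id]
    gex <- annotation$exons[annotation$exons$transcript_id %in% g_tx, ]
    for (i in seq_len(nrow(tex))) {
      for (j in seq_len(nrow(gex))) {
        if (.iv_overlap(tex$start[i], tex$end[i],
                        gex$start[j], gex$end[j])) {
          has_sense <- TRUE
        }
      }
    }
    # introns of the merged gene exon set
    m <- gex[order(gex$start), , drop = FALSE]
    merged <- list()
    for (j in seq_len(nrow(m))) {
      if (length(merged) > 0 &&
          m$start[j] <= merged[[length(merged)]][2] + 1) {
        merged[[length(merged)]][2] <- max(merged[[length(merged)]][2],
                                           m$end[j])
      } else {
        merged[[length(merged) + 1]] <- c(m$start[j], m$end[j])
      }
    }
    if (length(merged) >= 2) {
      for (j in seq_len(length(merged) - 1)) {
        i_start <- merged[[j]][2] + 1
        i_end <- merged[[j + 1]][1] - 1
        if (i_start <= i_end && span[1] >= i_start && span[2] <= i_end) {
          has_contain <- TRUE
        }
      }
    }
  }
  if (has_sense) return("sense")
  if (has_anti) return("antisense")
  if (has_contain || has_same_span) return("intronic")
  "lincRNA"
}

# --- brute-force longest-ORF oracle ----------------------------------------

# every (ATG, stop) pair in all three frames, maximal nt length
oracle_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  for (s in seq_len(max(n - 5, 0))) {
    if (substr(seq, s, s + 2) != "ATG") next
    e <- s + 3
    while (e + 2 <= n) {
      cod <- substr(seq, e, e + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, e + 2 - s + 1)
        break
      }
      e <- e + 3
    }
  }
  as.integer(best)
}

# --- random small annotation for classifier property tests -----------------

# a handful of genes with random exon structures plus one free transcript
# placed anywhere (overlaps arbitrary); returns the annotation and the
# transcript id to classify
random_annotation <- function() {
  n_genes <- sample(1:3, 1)
  genes <- list(); txs <- list(); exons <- list()
  for (g in seq_len(n_genes)) {
    n_ex <- sample(1:3, 1)
    start <- sample(1:3000, 1)
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    pos <- start
    for (i in seq_len(n_ex)) {
      ex_start[i] <- pos
      ex_end[i] <- pos + sample(50:300, 1)
      pos <- ex_end[i] + sample(100:600, 1)
    }
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("g%d", g)
    genes[[g]] <- tibble::tibble(gene_id = gid, chromosome = "chr",
                                 strand = strand, start = ex_start[1],
                                 end = ex_end[n_ex],
                                 biotype = "protein_coding")
    txs[[g]] <- tibble::tibble(transcript_id = paste0("t", g),
                               gene_id = gid, chromosome = "chr",
                               strand = strand, biotype = "protein_coding")
    exons[[g]] <- tibble::tibble(transcript_id = paste0("t", g),
                                 start = ex_start, end = ex_end)
  }
  n_ex <- sample(1:3, 1)
  pos <- sample(1:4000, 1)
  l_start <- integer(n_ex); l_end <- integer(n_ex)
  for (i in seq_len(n_ex)) {
    l_start[i] <- pos
    l_end[i] <- pos + sample(30:250, 1)
    pos <- l_end[i] + sample(30:400, 1)
  }
  txs[[n_genes + 1]] <- tibble::tibble(transcript_id = "lnc",
                                       gene_id = NA_character_,
                                       chromosome = "chr",
                                       strand = sample(c("+", "-"), 1),
                                       biotype = "lncRNA")
  exons[[n_genes + 1]] <- tibble::tibble(transcript_id = "lnc",
                                         start = l_start, end = l_end)
  genome_annotation(dplyr::bind_rows(genes), dplyr::bind_rows(txs),
                    dplyr::bind_rows(exons))
}

# --- small fixture builders ------------------------------------------------

# a fast, small simulation config for pipeline-level tests
quick_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed, chrom_length = 1e6, n_genes_per_chrom = 10,
    lnc_class_counts = c(lincRNA = 8, intronic = 4, sense = 3,
                         antisense = 3),
    te_families = c("copia", "jockey"), n_te_per_family = 3,
    decoy_counts = c(single_exon = 2, short = 2, coding = 2, homology = 2),
    de_pattern_counts = c(both_up = 2, both_down = 2, F_up_M_down = 1,
                          F_down_M_up = 1, F_up = 1, F_down = 1,
                          M_up = 1, M_down = 1),
    n_coexpr_pairs = 3,
    embryo = list(n_per_group = 5, probe_mean_wt = c(100, 100, 100),
                  probe_mean_mut = c(95, 75, 55), probe_sd = 10,
                  dapi_mean = 50, dapi_sd = 5)
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# build a genome_annotation from a compact transcript spec list:
# list(id, gene (or NA), chrom, strand, biotype, exons = matrix/list of
# c(start, end))
make_annotation <- function(genes, tx_specs) {
  txs <- dplyr::bind_rows(lapply(tx_specs, function(s) {
    tibble::tibble(transcript_id = s$id,
                   gene_id = if (is.null(s$gene)) NA_character_ else s$gene,
                   chromosome = s$chrom, strand = s$strand,
                   biotype = s$biotype)
  }))
  exons <- dplyr::bind_rows(lapply(tx_specs, function(s) {
    ex <- do.call(rbind, s$exons)
    tibble::tibble(transcript_id = s$id, start = ex[, 1], end = ex[, 2])
  }))
  genome_annotation(genes, txs, exons)
}

toy_count_matrix <- function(mat, genotype, sex = "F") {
  samples <- tibble::tibble(
    sample_id = colnames(mat), genotype = genotype, sex = sex,
    replicate = stats::ave(seq_along(genotype), genotype, sex,
                           FUN = seq_along))
  count_matrix(mat, samples)
}
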