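# Strand-aware positional classification of lncRNAs against protein-coding
# gene models. The four classes follow the standard taxonomy: lincRNA
# (intergenic: zero overlap with any protein-coding gene span), intronic
# (inside a gene intron with no exonic overlap), sense (same-strand
# exon-to-exon overlap) and antisense (opposite-strand overlap).
#
# Precedence when a transcript relates to several genes in different ways:
# sense > antisense > intronic > lincRNA — exonic same-strand overlap is
# the strongest relation, and any opposite-strand overlap outranks mere
# intron residency. A same-strand overlap that touches only intronic
# sequence without being contained in a single intron is also labelled
# intronic (evidence kind "intron_overlap"); this closes the taxonomy so a
# lincRNA call always guarantees zero gene-span overlap.

.LNC_CLASSES <- c("lincRNA", "intronic", "sense", "antisense")

# protein-coding gene geometry: spans, merged exons, introns (as tibbles
# with a gene index), reused by the classifier
.gene_geometry <- function(annotation) {
  pc <- annotation$genes[annotation$genes$biotype == "protein_coding", ,
                         drop = FALSE]
  tx <- annotation$transcripts
  pc_tx <- tx[!is.na(tx$gene_id) & tx$gene_id %in% pc$gene_id, ,
              drop = FALSE]
  ex <- annotation$exons[annotation$exons$transcript_id %in%
                           pc_tx$transcript_id, , drop = FALSE]
  ex$gene_id <- pc_tx$gene_id[match(ex$transcript_id, pc_tx$transcript_id)]

  span_gr <- GenomicRanges::GRanges(pc$chromosome,
                                    IRanges::IRanges(pc$start, pc$end))
  ex_gr <- GenomicRanges::GRanges(
    pc$chromosome[match(ex$gene_id, pc$gene_id)],
    IRanges::IRanges(ex$start, ex$end))
  S4Vectors::mcols(ex_gr)$gene_idx <- match(ex$gene_id, pc$gene_id)
  # merge exons per gene, then introns = within-span gaps
  ex_by_gene <- GenomicRanges::split(ex_gr, S4Vectors::mcols(ex_gr)$gene_idx)
  merged <- GenomicRanges::reduce(ex_by_gene)
  intron_list <- lapply(seq_along(merged), function(i) {
    g_idx <- as.integer(names(merged)[i])
    m <- merged[[i]]
    if (length(m) < 2) return(NULL)
    st <- GenomicRanges::end(m)[-length(m)] + 1L
    en <- GenomicRanges::start(m)[-1] - 1L
    keep <- st <= en
    if (!any(keep)) return(NULL)
    tibble::tibble(gene_idx = g_idx, start = st[keep], end = en[keep])
  })
  introns <- dplyr::bind_rows(intron_list)
  intron_gr <- if (nrow(introns) == 0) {
    GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(pc$chromosome[introns$gene_idx],
                                 IRanges::IRanges(introns$start, introns$end))
    S4Vectors::mcols(gr)$gene_idx <- introns$gene_idx
    gr
  }
  merged_flat <- unlist(merged)
  S4Vectors::mcols(merged_flat)$gene_idx <- as.integer(names(merged_flat))
  list(genes = pc, span_gr = span_gr, exon_gr = merged_flat,
       intron_gr = intron_gr)
}

#' Classify lncRNA transcripts by genomic position
#'
#' Assigns each transcript one of the four positional classes by the
#' precedence sense > antisense > intronic > lincRNA (see the package
#' vignette for the rationale). Overlap is computed on exon intervals for
#' the sense test and on gene spans for the antisense and lincRNA tests,
#' matching the class definitions.
#'
#' @param lnc A [genome_annotation()] holding the transcripts to classify
#'   (all of them are classified), or a character vector of transcript ids
#'   to classify within `annotation`.
#' @param annotation The reference [genome_annotation()] carrying the
#'   protein-coding gene models.
#' @return Tibble: `transcript_id`, `class`, `evidence_gene` (the
#'   overlapping gene chosen deterministically, `NA` for lincRNA),
#'   `evidence_kind` (`none`, `intron_containment`, `intron_overlap`,
#'   `exonic_same_strand`, `opposite_strand`).
#' @export
classify_lncrnas <- function(lnc, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (inherits(lnc, "genome_annotation")) {
    lnc_tx <- lnc$transcripts
    lnc_ex <- lnc$exons
  } else {
    lnc_tx <- annotation$transcripts[
      annotation$transcripts$transcript_id %in% lnc, , drop = FALSE]
    if (nrow(lnc_tx) < length(unique(lnc))) {
      stop("transcript id(s) absent from annotation: ",
           paste(utils::head(setdiff(lnc, lnc_tx$transcript_id), 5),
                 collapse = ", "), call. = FALSE)
    }
    lnc_ex <- annotation$exons[annotation$exons$transcript_id %in% lnc, ,
                               drop = FALSE]
  }
  if (nrow(lnc_tx) == 0) {
    return(tibble::tibble(transcript_id = character(), class = character(),
                          evidence_gene = character(),
                          evidence_kind = character()))
  }
  unknown_chrom <- setdiff(lnc_tx$chromosome, annotation$chromosomes)
  if (length(unknown_chrom) > 0) {
    stop("transcript chromosome(s) absent from annotation: ",
         paste(unknown_chrom, collapse = ", "), call. = FALSE)
  }

  geom <- .gene_geometry(annotation)
  n <- nrow(lnc_tx)
  class <- rep("lincRNA", n)
  ev_gene <- rep(NA_character_, n)
  ev_kind <- rep("none", n)

  if (nrow(geom$genes) > 0) {
    span_gr <- GenomicRanges::GRanges(
      lnc_tx$chromosome, IRanges::IRanges(lnc_tx$tx_start, lnc_tx$tx_end))
    ex_gr <- GenomicRanges::GRanges(
      lnc_tx$chromosome[match(lnc_ex$transcript_id, lnc_tx$transcript_id)],
      IRanges::IRanges(lnc_ex$start, lnc_ex$end))
    ex_tx_idx <- match(lnc_ex$transcript_id, lnc_tx$transcript_id)
    g_strand <- geom$genes$strand
    t_strand <- lnc_tx$strand

    pick <- function(cur, tx_idx, gene_idx, kind, label) {
      # first qualifying (transcript, gene) pair per transcript, gene id
      # tie-broken alphabetically for determinism
      if (length(tx_idx) == 0) return(cur)
      ord <- order(tx_idx, geom$genes$gene_id[gene_idx])
      tx_idx <- tx_idx[ord]; gene_idx <- gene_idx[ord]
      firsts <- !duplicated(tx_idx)
      sel <- tx_idx[firsts]
      open <- cur[sel] == "lincRNA"   # not yet claimed by a stronger rule
      sel <- sel[open]
      cur[sel] <- label
      ev_gene[sel] <<- geom$genes$gene_id[gene_idx[firsts][open]]
      ev_kind[sel] <<- kind
      cur
    }

    # (1) sense: exon-to-exon overlap, same strand
    h <- GenomicRanges::findOverlaps(ex_gr, geom$exon_gr,
                                     ignore.strand = TRUE)
    ti <- ex_tx_idx[S4Vectors::queryHits(h)]
    gi <- S4Vectors::mcols(geom$exon_gr)$gene_idx[S4Vectors::subjectHits(h)]
    same <- t_strand[ti] == g_strand[gi]
    class <- pick(class, ti[same], gi[same], "exonic_same_strand", "sense")

    # (2) antisense: any span overlap, opposite strand
    h <- GenomicRanges::findOverlaps(span_gr, geom$span_gr,
                                     ignore.strand = TRUE)
    ti <- S4Vectors::queryHits(h)
    gi <- S4Vectors::subjectHits(h)
    opp <- t_strand[ti] != g_strand[gi]
    class <- pick(class, ti[opp], gi[opp], "opposite_strand", "antisense")

    # (3) intronic: full containment in a single intron ...
    if (length(geom$intron_gr) > 0) {
      h <- GenomicRanges::findOverlaps(span_gr, geom$intron_gr,
                                       type = "within",
                                       ignore.strand = TRUE)
      ti <- S4Vectors::queryHits(h)
      gi <- S4Vectors::mcols(geom$intron_gr)$gene_idx[
        S4Vectors::subjectHits(h)]
      class <- pick(class, ti, gi, "intron_containment", "intronic")
    }
    # ... or any remaining same-strand span overlap (necessarily intronic
    # sequence only, since the sense rule failed)
    h <- GenomicRanges::findOverlaps(span_gr, geom$span_gr,
                                     ignore.strand = TRUE)
    ti <- S4Vectors::queryHits(h)
    gi <- S4Vectors::subjectHits(h)
    same <- t_strand[ti] == g_strand[gi]
    class <- pick(class, ti[same], gi[same], "intron_overlap", "intronic")
  }

  tibble::tibble(transcript_id = lnc_tx$transcript_id, class = class,
                 evidence_gene = ev_gene, evidence_kind = ev_kind)
}

#' Class proportions of a set of lncRNA labels
#'
#' @param labels Character vector of class labels, or the tibble returned
#'   by [classify_lncrnas()].
#' @return Tibble with one row per class (all four always present):
#'   `class`, `n`, `fraction` (sums to 1), `percent` (fraction, rounded to
#'   one decimal).
#' @export
class_proportions <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$class
  if (length(labels) == 0) stop("no labels supplied", call. = FALSE)
  bad <- setdiff(unique(labels), .LNC_CLASSES)
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- vapply(.LNC_CLASSES, function(cl) sum(labels == cl), integer(1))
  tibble::tibble(
    class = .LNC_CLASSES,
    n = unname(n),
    fraction = unname(n) / length(labels),
    percent = round(100 * unname(n) / length(labels), 1)
  )
}

#' Exon-count, length and chromosome summaries per biotype
#'
#' Bins transcripts by exon count and length, and tallies them per
#' chromosome arm, the standard structural comparison between mRNAs and
#' lncRNAs.
#'
#' @param transcripts Transcript tibble with `biotype`, `exon_count`,
#'   `length`, `chromosome` (as in `genome_annotation$transcripts`).
#' @param exon_bins Upper edges of the exon-count bins; counts at or above
#'   the last edge are pooled (default bins 1, 2, 3, 4, >=5).
#' @param length_breaks Internal breakpoints of the length bins (default
#'   <1000, 1000-3000, >3000 nt).
#' @param arms Chromosomes reported individually; everything else is
#'   grouped as `"other"`.
#' @return List of two tibbles: `structure` (biotype x exon bin x length
#'   bin counts) and `chromosome` (biotype x arm counts).
#' @export
summarize_structure <- function(transcripts,
                                exon_bins = c(1, 2, 3, 4, 5),
                                length_breaks = c(1000, 3000),
                                arms = c("2L", "2R", "3L", "3R", "4", "X")) {
  transcripts <- tibble::as_tibble(transcripts)
  last <- exon_bins[length(exon_bins)]
  exon_labels <- c(as.character(exon_bins[-length(exon_bins)]),
                   paste0(">=", last))
  len_labels <- c(paste0("<", length_breaks[1]),
                  if (length(length_breaks) > 1) {
                    paste(length_breaks[-length(length_breaks)],
                          length_breaks[-1], sep = "-")
                  },
                  paste0(">", length_breaks[length(length_breaks)]))
  # bins: [0, b1), [b1, b2], ..., (bk, Inf) — internal upper edges inclusive
  len_bin_of <- function(len) {
    idx <- findInterval(len, length_breaks) + 1L
    on_upper <- len %in% length_breaks[-1]
    idx[on_upper] <- idx[on_upper] - 1L
    len_labels[idx]
  }
  out <- transcripts |>
    dplyr::mutate(
      exon_bin = exon_labels[pmin(.data$exon_count, last)],
      length_bin = len_bin_of(.data$length)
    ) |>
    dplyr::count(.data$biotype, .data$exon_bin, .data$length_bin,
                 name = "n") |>
    dplyr::arrange(.data$biotype, .data$exon_bin, .data$length_bin)
  chrom <- transcripts |>
    dplyr::mutate(arm = ifelse(.data$chromosome %in% arms,
                               .data$chromosome, "other")) |>
    dplyr::count(.data$biotype, .data$arm, name = "n") |>
    dplyr::arrange(.data$biotype, .data$arm)
  list(structure = out, chromosome = chrom)
}
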