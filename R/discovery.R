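# Novel-transcript filter-and-prediction chain. Candidate transcripts pass
# a structural filter (>=2 exons, >=200 nt), a coding-potential stage, and
# a homology stage; noncoding survivors become novel lncRNA candidates,
# coding transcripts become novel mRNA candidates. The external scoring
# engines this field uses (CPC-style classifiers, Pfam/NR scans) are
# ingested as tabular hit files; a naive longest-ORF rule is shipped so the
# chain also runs hermetically.

#' Structural filter: exon count and transcript length
#'
#' Keeps transcripts with at least `min_exons` exons AND length at least
#' `min_length` nt (both thresholds inclusive). Single-exon transcripts are
#' removed with reason `structural_exon`; multi-exon transcripts shorter
#' than the floor with reason `structural_length`.
#'
#' @param transcripts Transcript tibble with `transcript_id`, `exon_count`,
#'   `length` columns (as in `genome_annotation$transcripts`).
#' @param min_exons,min_length Inclusive thresholds (defaults 2 and 200 nt).
#' @return Tibble `transcript_id`, `kept`, `reason` (`NA` when kept).
#' @export
structural_filter <- function(transcripts, min_exons = 2, min_length = 200) {
  transcripts <- tibble::as_tibble(transcripts)
  tibble::tibble(
    transcript_id = transcripts$transcript_id,
    kept = transcripts$exon_count >= min_exons &
      transcripts$length >= min_length,
    reason = dplyr::case_when(
      transcripts$exon_count < min_exons ~ "structural_exon",
      transcripts$length < min_length ~ "structural_length",
      TRUE ~ NA_character_
    )
  )
}

#' Longest open reading frame of a mature transcript sequence
#'
#' Scans the three forward-strand reading frames of the spliced sequence
#' for ATG...stop ORFs (the mature transcript is already strand-resolved,
#' so only the forward strand is read). Returns the longest ORF length in
#' nucleotides, stop codon included; 0 when no complete ORF exists.
#'
#' @param seq A single nucleotide string over A, C, G, T, N.
#' @return Integer ORF length in nt.
#' @export
longest_orf <- function(seq) {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  for (frame in 0:2) {
    i <- frame + 1L
    codons <- substring(seq, seq(i, n - 2, by = 3),
                        seq(i + 2, n, by = 3))
    if (length(codons) == 0) next
    start_pos <- which(codons == "ATG")
    stop_pos <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (s in start_pos) {
      stops_after <- stop_pos[stop_pos > s]
      if (length(stops_after) == 0) next
      best <- max(best, (stops_after[1] - s + 1L) * 3L)
    }
  }
  best
}

#' Naive coding-potential filter
#'
#' A transparent longest-ORF rule standing in for an external
#' coding-potential classifier: a transcript is called `coding` when its
#' longest forward-strand ORF reaches `min_codons` codons (start and stop
#' included) OR covers more than `max_coverage` of the transcript length.
#' Externally computed coding-potential hit tables, when supplied to
#' [run_discovery()], take precedence over this rule.
#'
#' @param sequences Named character vector of mature transcript sequences.
#' @param min_codons ORF length (codons) at which a transcript is called
#'   coding (default 100).
#' @param max_coverage ORF nt-coverage fraction above which a transcript is
#'   called coding (default 0.35, strict).
#' @return Tibble `transcript_id`, `orf_nt`, `orf_codons`, `coverage`,
#'   `verdict` (`"coding"` or `"noncoding"`).
#' @export
naive_coding_filter <- function(sequences, min_codons = 100,
                                max_coverage = 0.35) {
  if (length(sequences) == 0) {
    return(tibble::tibble(transcript_id = character(), orf_nt = integer(),
                          orf_codons = integer(), coverage = double(),
                          verdict = character()))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by transcript id", call. = FALSE)
  }
  orf <- unname(vapply(sequences, longest_orf, integer(1)))
  cov <- orf / unname(nchar(sequences))
  tibble::tibble(
    transcript_id = names(sequences),
    orf_nt = orf,
    orf_codons = orf %/% 3L,
    coverage = cov,
    verdict = ifelse(orf %/% 3L >= min_codons | cov > max_coverage,
                     "coding", "noncoding")
  )
}

#' Homology filter against external hit tables
#'
#' Removes a candidate when any hit from any supplied source has
#' E-value strictly below `e_max` (default 1e-5): a hit at exactly the
#' threshold is kept.
#'
#' @param candidates Character vector of transcript ids.
#' @param hits Hit tibble(s) as from [read_hits()] (may be a single tibble
#'   or a list of them; rows from all sources are pooled).
#' @param e_max Strict significance threshold (default 1e-5).
#' @return Tibble `transcript_id`, `kept`.
#' @export
homology_filter <- function(candidates, hits, e_max = 1e-5) {
  if (is.data.frame(hits)) hits <- list(hits)
  all_hits <- dplyr::bind_rows(hits)
  sig <- if (nrow(all_hits) > 0) {
    unique(all_hits$transcript_id[all_hits$e_value < e_max])
  } else character()
  tibble::tibble(transcript_id = candidates,
                 kept = !candidates %in% sig)
}

#' Run the full novel-transcript discovery chain
#'
#' Applies, in order: the structural filter, the coding stage (external
#' coding-potential hits when supplied, the naive ORF rule otherwise), and
#' the homology stage. Each filter is a pure per-transcript predicate, so
#' the final sets do not depend on stage order. Transcripts present in a
#' supplied reference annotation bypass discovery and keep their reference
#' biotype.
#'
#' @param assembled A [genome_annotation()] of candidate transcripts.
#' @param sequences Named character vector of mature sequences (required
#'   unless coding-potential hits cover the coding stage).
#' @param hits A tibble or list of tibbles from [read_hits()]. Rows with
#'   `source == "coding_potential"` drive the coding stage (a significant
#'   hit means coding); all other sources feed the homology stage.
#' @param reference Optional reference [genome_annotation()]; candidate ids
#'   found in it are set aside as known.
#' @param min_exons,min_length,min_codons,max_coverage,e_max Stage
#'   thresholds; see the individual filters.
#' @return An object of class `discovery_result`: list with
#'   `novel_lncRNA`, `novel_mRNA`, `known` (id vectors) and `audit`, a
#'   tibble giving every input transcript exactly one fate
#'   (`novel_lncRNA`, `novel_mRNA`, `known`, or the reason it was removed:
#'   `structural_exon`, `structural_length`, `homology`).
#' @export
run_discovery <- function(assembled, sequences = NULL, hits = NULL,
                          reference = NULL,
                          min_exons = 2, min_length = 200,
                          min_codons = 100, max_coverage = 0.35,
                          e_max = 1e-5) {
  stopifnot(inherits(assembled, "genome_annotation"))
  tx <- assembled$transcripts
  if (nrow(tx) == 0) {
    res <- list(novel_lncRNA = character(), novel_mRNA = character(),
                known = character(),
                audit = tibble::tibble(transcript_id = character(),
                                       fate = character()))
    return(structure(res, class = "discovery_result"))
  }

  known <- character()
  if (!is.null(reference)) {
    known <- intersect(tx$transcript_id, reference$transcripts$transcript_id)
  }
  cand <- tx[!tx$transcript_id %in% known, , drop = FALSE]
  fate <- stats::setNames(rep(NA_character_, nrow(cand)),
                          cand$transcript_id)

  st <- structural_filter(cand, min_exons, min_length)
  fate[st$transcript_id[!st$kept]] <- st$reason[!st$kept]
  surv <- st$transcript_id[st$kept]

  # coding stage: external coding-potential hits override the naive rule
  if (is.data.frame(hits)) hits <- list(hits)
  all_hits <- if (is.null(hits)) {
    tibble::tibble(transcript_id = character(), e_value = double(),
                   source = character())
  } else dplyr::bind_rows(hits)
  cp_hits <- all_hits[all_hits$source == "coding_potential", , drop = FALSE]
  hom_hits <- all_hits[all_hits$source != "coding_potential", , drop = FALSE]

  if (nrow(cp_hits) > 0) {
    coding_ids <- intersect(surv,
                            unique(cp_hits$transcript_id[cp_hits$e_value <
                                                           e_max]))
  } else {
    if (is.null(sequences)) {
      stop("sequences are required when no coding_potential hits are supplied",
           call. = FALSE)
    }
    missing <- setdiff(surv, names(sequences))
    if (length(missing) > 0) {
      stop("sequence missing for transcript(s): ",
           paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
    }
    ver <- naive_coding_filter(sequences[surv], min_codons, max_coverage)
    coding_ids <- ver$transcript_id[ver$verdict == "coding"]
  }

  noncoding <- setdiff(surv, coding_ids)
  hom <- homology_filter(noncoding, hom_hits, e_max)
  fate[hom$transcript_id[!hom$kept]] <- "homology"
  lnc <- hom$transcript_id[hom$kept]

  fate[coding_ids] <- "novel_mRNA"
  fate[lnc] <- "novel_lncRNA"
  audit <- tibble::tibble(
    transcript_id = c(names(fate), known),
    fate = c(unname(fate), rep("known", length(known)))
  ) |>
    dplyr::arrange(.data$transcript_id)

  structure(
    list(novel_lncRNA = sort(lnc), novel_mRNA = sort(coding_ids),
         known = sort(known), audit = audit),
    class = "discovery_result"
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(
    "<discovery_result> %d novel lncRNA, %d novel mRNA, %d known, %d removed\n",
    length(x$novel_lncRNA), length(x$novel_mRNA), length(x$known),
    sum(!x$audit$fate %in% c("novel_lncRNA", "novel_mRNA", "known"))))
  removed <- x$audit$fate[!x$audit$fate %in%
                            c("novel_lncRNA", "novel_mRNA", "known")]
  if (length(removed) > 0) {
    tb <- table(removed)
    cat("  removed by:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname run_discovery
#' @param x A `discovery_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.discovery_result <- function(x, ...) x$audit
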