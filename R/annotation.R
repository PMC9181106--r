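#' Construct a genome annotation object
#'
#' The central container flowing through discovery and classification: a set
#' of gene models plus exon-structured transcript models, all in 1-based
#' inclusive coordinates on the standard *Drosophila* chromosome arms
#' (2L, 2R, 3L, 3R, 4, X) or any other named sequence.
#'
#' @param genes Data frame with columns `gene_id`, `chromosome`, `strand`
#'   (`"+"` or `"-"`), `start`, `end`, `biotype`
#'   (`"protein_coding"`, `"lncRNA"`, `"TE"` or `"other"`).
#' @param transcripts Data frame with columns `transcript_id`, `gene_id`
#'   (`NA` allowed for novel assemblies), `chromosome`, `strand`, `biotype`.
#' @param exons Data frame with columns `transcript_id`, `start`, `end`
#'   (1-based inclusive).
#'
#' @return An object of class `genome_annotation`: a list with tibbles
#'   `genes`, `transcripts` (augmented with `exon_count` and `length`, the
#'   summed exon length in nt) and `exons` (sorted by start within each
#'   transcript).
#'
#' @details Validation enforces the structural invariants: `start <= end`
#'   for every exon, exon intervals per transcript sorted and
#'   non-overlapping, strand defined for every transcript, and exons inside
#'   the host gene span when a `gene_id` is present.
#'
#' @export
genome_annotation <- function(genes, transcripts, exons) {
  genes <- tibble::as_tibble(genes)
  transcripts <- tibble::as_tibble(transcripts)
  exons <- tibble::as_tibble(exons)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(genes, c("gene_id", "chromosome", "strand", "start", "end", "biotype"),
       "`genes`")
  need(transcripts, c("transcript_id", "gene_id", "chromosome", "strand",
                      "biotype"), "`transcripts`")
  need(exons, c("transcript_id", "start", "end"), "`exons`")

  if (anyDuplicated(genes$gene_id) > 0) {
    stop("duplicated gene_id in `genes`", call. = FALSE)
  }
  if (anyDuplicated(transcripts$transcript_id) > 0) {
    dup <- unique(transcripts$transcript_id[duplicated(transcripts$transcript_id)])
    stop("duplicated transcript_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- exons$end < exons$start
  if (any(bad)) {
    stop(sprintf("exon with end < start for transcript(s): %s",
                 paste(unique(exons$transcript_id[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(is.na(transcripts$strand)) ||
      !all(transcripts$strand %in% c("+", "-"))) {
    stop("every transcript must have strand '+' or '-'", call. = FALSE)
  }
  orphan <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(orphan) > 0) {
    stop("exons reference unknown transcript_id: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }

  exons <- dplyr::arrange(exons, .data$transcript_id, .data$start)
  ovl <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::filter(dplyr::n() > 1,
                  dplyr::lead(.data$start) <= .data$end) |>
    dplyr::ungroup()
  if (nrow(ovl) > 0) {
    stop("overlapping exons within transcript(s): ",
         paste(unique(ovl$transcript_id), collapse = ", "), call. = FALSE)
  }

  summ <- if (nrow(exons) == 0) {
    tibble::tibble(transcript_id = character(), exon_count = integer(),
                   length = integer(), tx_start = integer(),
                   tx_end = integer())
  } else {
    exons |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::summarise(exon_count = dplyr::n(),
                       length = sum(.data$end - .data$start + 1L),
                       tx_start = min(.data$start),
                       tx_end = max(.data$end),
                       .groups = "drop")
  }
  transcripts <- transcripts |>
    dplyr::select(!dplyr::any_of(c("exon_count", "length", "tx_start", "tx_end"))) |>
    dplyr::left_join(summ, by = "transcript_id")
  if (any(is.na(transcripts$exon_count))) {
    stop("transcript(s) without exons: ",
         paste(transcripts$transcript_id[is.na(transcripts$exon_count)],
               collapse = ", "), call. = FALSE)
  }

  # exons must lie within the host gene span when the gene is known
  with_gene <- dplyr::inner_join(
    transcripts, genes,
    by = "gene_id", suffix = c("", ".gene")
  )
  if (nrow(with_gene) > 0) {
    out_of_span <- with_gene$tx_start < with_gene$start |
      with_gene$tx_end > with_gene$end
    if (any(out_of_span)) {
      stop("transcript exons outside the gene span for: ",
           paste(with_gene$transcript_id[out_of_span], collapse = ", "),
           call. = FALSE)
    }
  }

  structure(
    list(
      chromosomes = sort(unique(c(genes$chromosome, transcripts$chromosome))),
      genes = dplyr::arrange(genes, .data$gene_id),
      transcripts = dplyr::arrange(transcripts, .data$transcript_id),
      exons = exons
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d gene(s), %d transcript(s), %d exon(s) on %s\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
    paste(x$chromosomes, collapse = ", ")
  ))
  bt <- table(x$transcripts$biotype)
  cat("  transcript biotypes:",
      paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a count matrix with its sample sheet
#'
#' @param counts Non-negative integer matrix, transcripts in rows (rownames
#'   are transcript ids), samples in columns.
#' @param samples Data frame with columns `sample_id`, `genotype`
#'   (`"WT"` or `"ISWI"`), `sex` (`"F"` or `"M"`), `replicate`; one row per
#'   column of `counts`, in column order.
#'
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  samples <- tibble::as_tibble(samples)
  need <- setdiff(c("sample_id", "genotype", "sex", "replicate"),
                  names(samples))
  if (length(need) > 0) {
    stop("sample sheet is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("count matrix must carry transcript ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) > 0) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicated transcript id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integers (raw read counts, not normalized values)",
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!setequal(colnames(counts), samples$sample_id) ||
      ncol(counts) != nrow(samples)) {
    stop("sample sheet must cover every count column exactly once",
         call. = FALSE)
  }
  if (!all(samples$genotype %in% c("WT", "ISWI"))) {
    stop("genotype must be 'WT' or 'ISWI'", call. = FALSE)
  }
  if (!all(samples$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d transcript(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  grp <- dplyr::count(x$samples, .data$genotype, .data$sex)
  cat(paste(sprintf("  %s/%s: %d replicate(s)", grp$genotype, grp$sex, grp$n),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Convert exon coordinates between 1-based inclusive and 0-based half-open
#'
#' All coordinates in this package are 1-based inclusive (the GTF
#' convention). These helpers convert an exon table to the BED-style 0-based
#' half-open convention and back; the two are mutually inverse.
#'
#' @param exons Data frame with `start` and `end` columns.
#' @return The exon table with converted coordinates.
#' @export
exons_to_half_open <- function(exons) {
  dplyr::mutate(exons, start = .data$start - 1L)
}

#' @rdname exons_to_half_open
#' @export
exons_to_one_based <- function(exons) {
  dplyr::mutate(exons, start = .data$start + 1L)
}
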