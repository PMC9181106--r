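# GTF and tabular IO. GTF parsing/writing is delegated to rtracklayer;
# this file enforces the package's coordinate and dialect conventions in
# one place.

.BIOTYPE_KEYS <- c("gene_biotype", "transcript_biotype", "gene_type",
                   "transcript_type", "biotype")

.canonical_biotype <- function(x) {
  x <- tolower(as.character(x))
  dplyr::case_when(
    is.na(x) ~ "other",
    x %in% c("protein_coding", "mrna") ~ "protein_coding",
    grepl("lncrna|lincrna|antisense|ncrna", x) ~ "lncRNA",
    grepl("^te$|transposable|transposon|repeat", x) ~ "TE",
    TRUE ~ "other"
  )
}

#' Read a genome annotation from a GTF file
#'
#' Parses transcript and exon records (1-based inclusive coordinates) into a
#' [genome_annotation()]. Two dialects are accepted: `"reference"` files
#' carry gene records and biotype attributes; `"assembled"` files
#' (StringTie-style candidate transcripts) may lack both, in which case gene
#' spans are inferred from the transcripts grouped under each `gene_id` and
#' biotypes default to `"other"`.
#'
#' @param path Path to a GTF file.
#' @param dialect `"reference"` or `"assembled"`.
#' @return A [genome_annotation()].
#' @details Feature types other than `gene`, `transcript` and `exon` are
#'   ignored with a message stating how many records were skipped. Exon rows
#'   lacking a `transcript_id` attribute are a parse error naming the
#'   offending record. A file with no transcript records yields an empty
#'   annotation with a warning.
#' @export
read_annotation <- function(path, dialect = c("reference", "assembled")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble::as_tibble(as.data.frame(gr, stringsAsFactors = FALSE))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  for (k in c("gene_id", "transcript_id", .BIOTYPE_KEYS)) {
    if (!k %in% names(df)) df[[k]] <- NA_character_
  }

  known <- df$type %in% c("gene", "transcript", "exon")
  if (any(!known)) {
    message(sum(!known), " record(s) of other feature types ignored")
    df <- df[known, , drop = FALSE]
  }

  no_tx <- df$type %in% c("transcript", "exon") & is.na(df$transcript_id)
  if (any(no_tx)) {
    stop("record(s) without transcript_id attribute at row(s): ",
         paste(utils::head(which(no_tx), 5), collapse = ", "), call. = FALSE)
  }

  biotype_of <- function(sub) {
    for (k in .BIOTYPE_KEYS) {
      v <- sub[[k]]
      if (any(!is.na(v))) return(.canonical_biotype(v[!is.na(v)][1]))
    }
    "other"
  }

  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) {
    warning("no transcript/exon records found; returning empty annotation")
    empty_tx <- tibble::tibble(transcript_id = character(),
                               gene_id = character(),
                               chromosome = character(), strand = character(),
                               biotype = character())
    return(genome_annotation(
      genes = tibble::tibble(gene_id = character(), chromosome = character(),
                             strand = character(), start = integer(),
                             end = integer(), biotype = character()),
      transcripts = empty_tx,
      exons = tibble::tibble(transcript_id = character(), start = integer(),
                             end = integer())
    ))
  }

  exons <- tibble::tibble(transcript_id = ex$transcript_id,
                          start = as.integer(ex$start),
                          end = as.integer(ex$end))

  tx_rows <- df[df$type == "transcript", , drop = FALSE]
  tx_attr <- ex |>
    dplyr::group_by(transcript_id = .data$transcript_id) |>
    dplyr::summarise(
      gene_id = dplyr::first(stats::na.omit(.data$gene_id))[1],
      chromosome = .data$seqnames[1],
      strand = .data$strand[1],
      .groups = "drop"
    )
  bt_by_tx <- vapply(split(ex, ex$transcript_id), biotype_of, character(1))
  tx_attr$biotype <- unname(bt_by_tx[tx_attr$transcript_id])
  # transcript records may refine gene_id/biotype when exon rows lack them
  if (nrow(tx_rows) > 0) {
    tr <- tibble::tibble(
      transcript_id = tx_rows$transcript_id,
      gene_id_tx = tx_rows$gene_id,
      biotype_tx = vapply(seq_len(nrow(tx_rows)),
                          function(i) biotype_of(tx_rows[i, ]), character(1))
    )
    tx_attr <- tx_attr |>
      dplyr::left_join(tr, by = "transcript_id") |>
      dplyr::mutate(
        gene_id = dplyr::coalesce(.data$gene_id, .data$gene_id_tx),
        biotype = dplyr::if_else(.data$biotype == "other" &
                                   !is.na(.data$biotype_tx),
                                 .data$biotype_tx, .data$biotype)
      ) |>
      dplyr::select(-"gene_id_tx", -"biotype_tx")
  }

  gene_rows <- df[df$type == "gene" & !is.na(df$gene_id), , drop = FALSE]
  if (nrow(gene_rows) > 0 && dialect == "reference") {
    genes <- tibble::tibble(
      gene_id = gene_rows$gene_id,
      chromosome = gene_rows$seqnames,
      strand = gene_rows$strand,
      start = as.integer(gene_rows$start),
      end = as.integer(gene_rows$end),
      biotype = vapply(seq_len(nrow(gene_rows)),
                       function(i) biotype_of(gene_rows[i, ]), character(1))
    )
  } else {
    # infer gene spans from the transcripts grouped under each gene_id
    span <- exons |>
      dplyr::inner_join(tx_attr, by = "transcript_id") |>
      dplyr::filter(!is.na(.data$gene_id)) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(chromosome = .data$chromosome[1],
                       strand = .data$strand[1],
                       start = min(.data$start), end = max(.data$end),
                       biotype = .data$biotype[1], .groups = "drop")
    genes <- span
  }

  genome_annotation(genes = genes, transcripts = tx_attr, exons = exons)
}

#' Write a genome annotation to GTF
#'
#' Emits transcript and exon records with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes; [read_annotation()] of the result round-trips
#' transcript structure (ids, strand, exon intervals) exactly.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  tx <- annotation$transcripts
  ex <- dplyr::left_join(annotation$exons,
                         dplyr::select(tx, "transcript_id", "gene_id",
                                       "chromosome", "strand", "biotype"),
                         by = "transcript_id")
  mk <- function(df, type) {
    GenomicRanges::GRanges(
      seqnames = df$chromosome,
      ranges = IRanges::IRanges(df$start, df$end),
      strand = df$strand,
      type = type,
      gene_id = ifelse(is.na(df$gene_id), df$transcript_id, df$gene_id),
      transcript_id = df$transcript_id,
      gene_biotype = df$biotype
    )
  }
  tx_gr <- mk(dplyr::rename(tx, start = "tx_start", end = "tx_end"),
              "transcript")
  ex_gr <- mk(ex, "exon")
  ord <- order(tx$transcript_id)
  out <- c(tx_gr[ord], ex_gr)
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read a raw count matrix and its sample sheet
#'
#' @param path Tab-separated count file: first column transcript ids, one
#'   column per sample.
#' @param sample_sheet Path to a tab-separated sample sheet with columns
#'   `sample_id`, `genotype` (WT/ISWI), `sex` (F/M), `replicate`.
#' @return A [count_matrix()], columns ordered as in the sample sheet.
#' @details Non-integer or negative counts, duplicated transcript ids, and
#'   sheet samples missing from the matrix are validation errors.
#' @export
read_counts <- function(path, sample_sheet) {
  for (p in c(path, sample_sheet)) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  # sex "F" must never be type-guessed as logical FALSE
  sheet <- readr::read_tsv(
    sample_sheet, show_col_types = FALSE,
    col_types = readr::cols(sample_id = "c", genotype = "c", sex = "c",
                            replicate = "i", .default = "c"))
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  missing <- setdiff(sheet$sample_id, colnames(mat))
  if (length(missing) > 0) {
    stop("sample(s) in sheet missing from count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(mat) || any(is.na(mat)) || any(mat != round(mat))) {
    stop("counts must be integers", call. = FALSE)
  }
  rownames(mat) <- ids
  count_matrix(mat[, sheet$sample_id, drop = FALSE], sheet)
}

#' Read an external hit table (coding potential or homology scan)
#'
#' Rows are retained verbatim; no E-value threshold is applied at read time
#' (thresholding happens in the discovery filters).
#'
#' @param path Tab-separated file whose first two columns are transcript id
#'   and E-value. A header line is detected and skipped if its second field
#'   is not numeric.
#' @param source One of `"coding_potential"`, `"pfam"`, `"nr"`,
#'   `"uniref90"`; tags every row.
#' @return A tibble with columns `transcript_id`, `e_value`, `source`.
#' @export
read_hits <- function(path,
                      source = c("coding_potential", "pfam", "nr", "uniref90")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(transcript_id = character(), e_value = double(),
                          source = character()))
  }
  first <- strsplit(lines[1], "\t")[[1]]
  if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    return(tibble::tibble(transcript_id = character(), e_value = double(),
                          source = character()))
  }
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2)) {
    stop("hit table rows need at least transcript_id and e_value columns",
         call. = FALSE)
  }
  ev <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (any(is.na(ev)) || any(!is.finite(ev))) {
    stop("unparsable e_value in hit table", call. = FALSE)
  }
  if (any(ev < 0)) stop("e_value must be non-negative", call. = FALSE)
  tibble::tibble(transcript_id = vapply(parts, `[[`, "", 1),
                 e_value = ev, source = source)
}

# Output schemas: column set, key columns for sorting, and which columns
# are floats (rendered at fixed precision so repeated writes are
# byte-identical).
.TABLE_SCHEMAS <- list(
  ratio_records = list(
    cols = c("transcript_id", "class", "stratum", "mean_wt", "mean_mut",
             "log2_ratio"),
    key = "transcript_id",
    float = c("mean_wt", "mean_mut", "log2_ratio")
  ),
  edges = list(
    cols = c("lncRNA_id", "mRNA_id", "r", "p", "sign"),
    key = c("lncRNA_id", "mRNA_id"),
    float = c("r", "p")
  ),
  de_results = list(
    cols = c("transcript_id", "base_mean", "log2_fc", "stat", "p", "padj",
             "call"),
    key = "transcript_id",
    float = c("base_mean", "log2_fc", "stat", "p", "padj")
  ),
  te_family_summary = list(
    cols = c("family", "n_de", "family_total", "proportion", "mean_base_mean",
             "rank_n_de", "rank_proportion", "rank_base_mean"),
    key = "family",
    float = c("proportion", "mean_base_mean")
  ),
  classes = list(
    cols = c("transcript_id", "class", "evidence_gene", "evidence_kind"),
    key = "transcript_id",
    float = character()
  ),
  medians = list(
    cols = c("stratum", "class", "n", "median_log2_ratio"),
    key = c("stratum", "class"),
    float = "median_log2_ratio"
  ),
  fish_stats = list(
    cols = c("stage", "mean_wt", "mean_mut", "t", "p", "label"),
    key = "stage",
    float = c("mean_wt", "mean_mut", "t", "p")
  ),
  histogram = list(
    cols = c("class", "bin_start", "bin_end", "frequency"),
    key = c("class", "bin_start"),
    float = c("bin_start", "bin_end", "frequency")
  )
)

#' Write an analysis table deterministically
#'
#' All tabular outputs go through one writer: tab-separated with a header,
#' columns in schema order, rows sorted by the schema's primary key, floats
#' rendered at fixed precision — so writing the same rows twice yields
#' byte-identical files.
#'
#' @param rows Data frame conforming to one of the named output schemas.
#' @param path Output path.
#' @param schema One of `r paste0('\x60', names(.TABLE_SCHEMAS), '\x60', collapse = ", ")`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, schema) {
  if (!schema %in% names(.TABLE_SCHEMAS)) {
    stop("unknown schema: ", schema, call. = FALSE)
  }
  sc <- .TABLE_SCHEMAS[[schema]]
  rows <- tibble::as_tibble(rows)
  miss <- setdiff(sc$cols, names(rows))
  if (length(miss) > 0) {
    stop("rows are missing field(s) for schema '", schema, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- rows[, sc$cols, drop = FALSE]
  rows <- dplyr::arrange(rows, dplyr::across(dplyr::all_of(sc$key)))
  for (f in sc$float) {
    rows[[f]] <- ifelse(is.na(rows[[f]]), "NA",
                        formatC(rows[[f]], digits = 8, format = "g"))
  }
  lines <- c(paste(sc$cols, collapse = "\t"),
             if (nrow(rows) > 0) {
               do.call(paste, c(lapply(rows, as.character), sep = "\t"))
             })
  writeLines(lines, path)
  invisible(path)
}
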