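# Count normalization and the dosage-framework ratio analysis: per-sample
# median-of-ratios size factors, per-transcript log2(mutant/WT) ratios with
# chromosome stratum and biotype class, histogram and stratified-median
# summaries, and the +-log2(3/2) genomic-balance reference lines.

#' Genomic-balance dosage reference lines
#'
#' The three reference lines framing a log2(mutant/WT) ratio distribution:
#' dosage compensation at 0 (ratio 1), the positive dosage effect at
#' +log2(3/2) = 0.58 (two decimals), and the inverse dosage effect at
#' -log2(3/2). The 3:2 ratio is the expression change expected when a
#' monosomic genomic balance acts on an unchanged target.
#'
#' @return Tibble: `line` (`compensation`, `positive_dosage`,
#'   `inverse_dosage`), `log2_ratio`.
#' @export
dosage_frame <- function() {
  tibble::tibble(
    line = c("compensation", "positive_dosage", "inverse_dosage"),
    log2_ratio = c(0, log2(3 / 2), -log2(3 / 2))
  )
}

#' Median-of-ratios size factors
#'
#' The standard library-size estimator for count matrices: a pseudo-
#' reference is built as the per-transcript geometric mean over samples
#' (using transcripts with no zero entry), and each sample's factor is the
#' median over those transcripts of count / geometric mean.
#'
#' @param counts A [count_matrix()] or a numeric matrix (transcripts x
#'   samples).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  mat <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  if (ncol(mat) < 2) stop("need at least 2 samples", call. = FALSE)
  all_pos <- rowSums(mat == 0) == 0
  if (!any(all_pos)) {
    stop(paste("no transcript has all-positive counts; a pseudo-reference",
               "over positive entries is required for such sparse data"),
         call. = FALSE)
  }
  ref <- mat[all_pos, , drop = FALSE]
  log_geo <- rowMeans(log(ref))
  apply(ref, 2, function(col) exp(stats::median(log(col) - log_geo)))
}

#' Normalize counts and compute baseMean
#'
#' Divides each sample's counts by its size factor; `baseMean` is the mean
#' of normalized counts across all samples of the matrix (the quantity the
#' TE expression filter thresholds).
#'
#' @param counts A [count_matrix()].
#' @param factors Size factors from [size_factors()]; computed if omitted.
#' @return List: `normalized` (numeric matrix), `samples` (the sample
#'   sheet), `base_mean` (tibble `transcript_id`, `base_mean`).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(factors)) factors <- size_factors(counts)
  stopifnot(length(factors) == ncol(counts$counts), all(factors > 0))
  norm <- sweep(counts$counts, 2, factors, "/")
  list(
    normalized = norm,
    samples = counts$samples,
    base_mean = tibble::tibble(transcript_id = rownames(norm),
                               base_mean = unname(rowMeans(norm)))
  )
}

#' Per-transcript log2(mutant/WT) ratio records
#'
#' For one sex, averages normalized counts over the mutant and wild-type
#' replicates and takes log2(mutant mean / WT mean). Transcripts whose two
#' group means do not both reach `min_mean` normalized counts are excluded
#' (not set to NA), keeping every retained ratio finite.
#'
#' @param normalized Result of [normalize_counts()].
#' @param sex `"F"` or `"M"`.
#' @param classes Optional tibble `transcript_id`, `class` (e.g. from
#'   [classify_lncrnas()], or biotypes); transcripts without an entry keep
#'   their annotation biotype when `annotation` is given, else class `NA`.
#' @param annotation Optional [genome_annotation()] supplying chromosome
#'   (for the X/autosome stratum) and fallback biotype. Without it, a
#'   `chromosomes` lookup tibble (`transcript_id`, `chromosome`) must be
#'   provided.
#' @param chromosomes Optional tibble `transcript_id`, `chromosome`.
#' @param min_mean Expression floor on both group means (default 1).
#' @return Tibble of ratio records: `transcript_id`, `class`, `stratum`
#'   (`"X"` or `"autosome"`), `mean_wt`, `mean_mut`, `log2_ratio`.
#' @export
group_log2_ratios <- function(normalized, sex, classes = NULL,
                              annotation = NULL, chromosomes = NULL,
                              min_mean = 1) {
  samples <- normalized$samples
  sel <- samples$sex == sex
  if (!any(sel)) stop("no samples for sex ", sex, call. = FALSE)
  mut <- sel & samples$genotype == "ISWI"
  wt <- sel & samples$genotype == "WT"
  if (!any(mut) || !any(wt)) {
    stop("both genotype groups must have replicates for sex ", sex,
         call. = FALSE)
  }
  mat <- normalized$normalized
  mean_mut <- rowMeans(mat[, mut, drop = FALSE])
  mean_wt <- rowMeans(mat[, wt, drop = FALSE])

  rec <- tibble::tibble(
    transcript_id = rownames(mat),
    mean_wt = unname(mean_wt),
    mean_mut = unname(mean_mut)
  )
  if (!is.null(annotation)) {
    tx <- annotation$transcripts
    rec$chromosome <- tx$chromosome[match(rec$transcript_id,
                                          tx$transcript_id)]
    rec$class <- tx$biotype[match(rec$transcript_id, tx$transcript_id)]
    rec$class[rec$class == "protein_coding"] <- "mRNA"
  } else if (!is.null(chromosomes)) {
    rec$chromosome <- chromosomes$chromosome[
      match(rec$transcript_id, chromosomes$transcript_id)]
    rec$class <- NA_character_
  } else {
    stop("supply `annotation` or a `chromosomes` lookup", call. = FALSE)
  }
  if (!is.null(classes)) {
    idx <- match(rec$transcript_id, classes$transcript_id)
    rec$class <- ifelse(is.na(idx), rec$class, classes$class[idx])
  }
  rec |>
    dplyr::filter(.data$mean_wt >= min_mean, .data$mean_mut >= min_mean) |>
    dplyr::mutate(
      stratum = ifelse(.data$chromosome == "X", "X", "autosome"),
      log2_ratio = log2(.data$mean_mut / .data$mean_wt)
    ) |>
    dplyr::select("transcript_id", "class", "stratum", "mean_wt",
                  "mean_mut", "log2_ratio")
}

#' Binned frequency curve of log2 ratios per class
#'
#' Relative frequencies (per class) over fixed-width bins; frequencies sum
#' to the fraction of that class's records falling inside `range`, and the
#' out-of-range mass is reported separately.
#'
#' @param records Ratio records from [group_log2_ratios()].
#' @param bin_width Bin width (default 0.1).
#' @param range Two-element range of the binned axis (default [-3, 3]);
#'   bins are left-closed, right-open.
#' @return List: `histogram` (tibble `class`, `bin_start`, `bin_end`,
#'   `bin_mid`, `n`, `frequency`) and `out_of_range` (tibble `class`, `n`,
#'   `fraction`).
#' @export
ratio_histogram <- function(records, bin_width = 0.1, range = c(-3, 3)) {
  if (nrow(records) == 0) stop("no ratio records", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  hist_tbl <- records |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(df, key) {
      inside <- df$log2_ratio >= range[1] & df$log2_ratio < range[2]
      idx <- findInterval(df$log2_ratio[inside], edges,
                          rightmost.closed = FALSE)
      n_bin <- tabulate(idx, nbins = length(edges) - 1)
      tibble::tibble(
        bin_start = edges[-length(edges)],
        bin_end = edges[-1],
        n = n_bin,
        frequency = n_bin / nrow(df)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_mid = (.data$bin_start + .data$bin_end) / 2,
                  .after = "bin_end")
  oor <- records |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = sum(.data$log2_ratio < range[1] | .data$log2_ratio >= range[2]),
      fraction = .data$n / dplyr::n(), .groups = "drop")
  list(histogram = hist_tbl, out_of_range = oor)
}

#' Median log2 ratio per (stratum, class) group
#'
#' The stratified-median summary of a ratio distribution. An optional id
#' subset (e.g. the X-linked transcription factors) restricts records
#' before grouping. Requested groups that turn out empty are omitted with a
#' warning.
#'
#' @param records Ratio records from [group_log2_ratios()].
#' @param subset Optional character vector of transcript ids to restrict to.
#' @return Tibble: `stratum`, `class`, `n`, `median_log2_ratio`, sorted.
#' @export
median_by_stratum <- function(records, subset = NULL) {
  if (!is.null(subset)) {
    dropped <- records[!records$transcript_id %in% subset, , drop = FALSE]
    records <- records[records$transcript_id %in% subset, , drop = FALSE]
    if (nrow(records) == 0) {
      warning("subset left no records; all groups omitted")
      return(tibble::tibble(stratum = character(), class = character(),
                            n = integer(), median_log2_ratio = double()))
    }
  }
  if (nrow(records) == 0) {
    warning("no records; all groups omitted")
    return(tibble::tibble(stratum = character(), class = character(),
                          n = integer(), median_log2_ratio = double()))
  }
  records |>
    dplyr::group_by(.data$stratum, .data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     median_log2_ratio = stats::median(.data$log2_ratio),
                     .groups = "drop") |>
    dplyr::arrange(.data$stratum, .data$class)
}

#' Compare two log2-ratio distributions
#'
#' Two-sample Kolmogorov-Smirnov test (asymptotic p), the package's
#' documented choice for comparing the mRNA and lncRNA ratio distributions
#' of a panel.
#'
#' @param records_a,records_b Numeric vectors of log2 ratios, or ratio-
#'   record tibbles (their `log2_ratio` column is used).
#' @return Tibble: `statistic` (D in [0, 1]), `p_value`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(records_a, records_b) {
  xa <- if (is.data.frame(records_a)) records_a$log2_ratio else records_a
  xb <- if (is.data.frame(records_b)) records_b$log2_ratio else records_b
  if (length(xa) < 2 || length(xb) < 2) {
    stop("both samples must have size >= 2", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(xa, xb, exact = FALSE))
  tibble::tibble(statistic = unname(ks$statistic),
                 p_value = ks$p.value,
                 n_a = length(xa), n_b = length(xb))
}
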