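# Transposable-element expression analysis: filter differentially
# expressed TE instances on expression level, aggregate to families, rank
# families on three criteria.

#' Filter DE TE instances on expression level
#'
#' An instance passes iff its DE call is not `ns` AND its baseMean exceeds
#' `basemean_min` strictly (an instance at exactly the threshold is
#' excluded).
#'
#' @param de DE tibble for TE instances (`transcript_id`, `call`).
#' @param base_mean Tibble `transcript_id`, `base_mean` (e.g. from
#'   [normalize_counts()]); must cover every instance in `de`.
#' @param basemean_min Strict expression threshold (default 500).
#' @return Tibble of passing instances: `transcript_id`, `call`,
#'   `base_mean`.
#' @export
filter_de_te <- function(de, base_mean, basemean_min = 500) {
  de <- tibble::as_tibble(de)
  idx <- match(de$transcript_id, base_mean$transcript_id)
  if (any(is.na(idx))) {
    stop("instance(s) missing a baseMean: ",
         paste(utils::head(de$transcript_id[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  }
  bm <- base_mean$base_mean[idx]
  keep <- de$call != "ns" & bm > basemean_min
  tibble::tibble(transcript_id = de$transcript_id[keep],
                 call = de$call[keep],
                 base_mean = bm[keep])
}

#' Family-level summary of passing TE instances
#'
#' Aggregates the filtered DE-TE instances per family: count, proportion of
#' the annotated family size, and mean baseMean of the passing instances.
#' Per-chromosome tallies of the passing instances are also returned.
#'
#' @param passing Result of [filter_de_te()].
#' @param families Tibble `transcript_id`, `family` covering every
#'   annotated instance (the denominator of the proportions) — and
#'   optionally `chromosome` for the location tally.
#' @return List: `summary` (tibble `family`, `n_de`, `family_total`,
#'   `proportion`, `mean_base_mean`) and `chromosome` (tibble `chromosome`,
#'   `n`, or NULL when no chromosome column is supplied).
#' @export
te_family_summary <- function(passing, families) {
  families <- tibble::as_tibble(families)
  unknown <- setdiff(passing$transcript_id, families$transcript_id)
  if (length(unknown) > 0) {
    stop("instance(s) with unknown family: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  fam_of <- families$family[match(passing$transcript_id,
                                  families$transcript_id)]
  totals <- dplyr::count(families, .data$family, name = "family_total")
  got <- tibble::tibble(family = fam_of, base_mean = passing$base_mean) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_de = dplyr::n(),
                     mean_base_mean = mean(.data$base_mean),
                     .groups = "drop")
  summary <- totals |>
    dplyr::left_join(got, by = "family") |>
    dplyr::mutate(
      n_de = dplyr::coalesce(.data$n_de, 0L),
      mean_base_mean = dplyr::coalesce(.data$mean_base_mean, 0),
      proportion = .data$n_de / .data$family_total
    ) |>
    dplyr::select("family", "n_de", "family_total", "proportion",
                  "mean_base_mean") |>
    dplyr::arrange(.data$family)
  chrom <- NULL
  if ("chromosome" %in% names(families)) {
    chrom <- families |>
      dplyr::filter(.data$transcript_id %in% passing$transcript_id) |>
      dplyr::count(.data$chromosome, name = "n") |>
      dplyr::arrange(.data$chromosome)
  }
  list(summary = summary, chromosome = chrom)
}

#' Rank TE families on three criteria
#'
#' Independent descending rankings by number of DE instances, proportion of
#' the family, and mean expression level (baseMean), each with an
#' alphabetical tie-break, plus a consensus flag marking families inside
#' the top `top_n` of all three lists.
#'
#' @param summary Family summary tibble from [te_family_summary()].
#' @param top_n Size of each top list (default 10).
#' @return List: `table` (the summary with `rank_n_de`, `rank_proportion`,
#'   `rank_base_mean`, `in_all_top`), and `top` (list of the three ranked
#'   family vectors, truncated to `top_n`).
#' @export
rank_te_families <- function(summary, top_n = 10) {
  if (nrow(summary) == 0) stop("no family summaries", call. = FALSE)
  rank_by <- function(v) {
    ord <- order(-v, summary$family)
    rk <- integer(length(v))
    rk[ord] <- seq_along(v)
    rk
  }
  tbl <- summary |>
    dplyr::mutate(
      rank_n_de = rank_by(.data$n_de),
      rank_proportion = rank_by(.data$proportion),
      rank_base_mean = rank_by(.data$mean_base_mean),
      in_all_top = .data$rank_n_de <= top_n &
        .data$rank_proportion <= top_n & .data$rank_base_mean <= top_n
    )
  top <- list(
    n_de = tbl$family[order(tbl$rank_n_de)][seq_len(min(top_n, nrow(tbl)))],
    proportion = tbl$family[order(tbl$rank_proportion)][
      seq_len(min(top_n, nrow(tbl)))],
    base_mean = tbl$family[order(tbl$rank_base_mean)][
      seq_len(min(top_n, nrow(tbl)))]
  )
  list(table = tbl, top = top)
}
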