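# Embryo fluorescence quantification: per-embryo RNA-probe / DAPI
# intensity ratios and a per-stage-group genotype comparison by pooled
# two-sample (Student) t-test with the conventional significance labels.

.FISH_STAGES <- c("St1-5", "St6-11", "St12-17")

#' Relative fluorescence intensity
#'
#' Probe-channel over DAPI-channel intensity per embryo; dividing by the
#' DAPI (DNA) signal calibrates away exposure and embryo-size differences,
#' so scaling both channels by a common factor leaves the ratio unchanged.
#'
#' @param measurements Tibble with `probe` and `dapi` columns (one row per
#'   embryo).
#' @return The input with a `ratio` column appended.
#' @export
relative_intensity <- function(measurements) {
  measurements <- tibble::as_tibble(measurements)
  if (any(measurements$dapi <= 0)) {
    stop("DAPI intensity must be > 0 for every embryo", call. = FALSE)
  }
  if (any(measurements$probe < 0)) {
    stop("probe intensity must be >= 0", call. = FALSE)
  }
  dplyr::mutate(measurements, ratio = .data$probe / .data$dapi)
}

#' Significance label for a p-value
#'
#' The conventional star mapping: `NS.` for p >= 0.05, `*` for p < 0.05,
#' `**` for p < 0.01, `***` for p < 0.001. Monotone: a smaller p never
#' yields a weaker label.
#'
#' @param p P-value(s).
#' @return Character label(s).
#' @export
significance_label <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "NS."
  )
}

#' Compare genotypes per embryonic stage group
#'
#' Equal-variance (Student) two-sample t-test on the per-embryo
#' probe/DAPI ratios, WT vs mutant, for each stage group present (or a
#' single requested one). When both groups are constant and equal the test
#' is degenerate; the comparison returns `NS.` with a warning instead of
#' NaN.
#'
#' @param measurements Embryo tibble with `genotype`, `stage`, `probe`,
#'   `dapi` (e.g. from [generate_embryo_table()]); ratios are computed
#'   internally.
#' @param stage Optional single stage group to compare; default all.
#' @param var_equal Pooled-variance Student t (default TRUE); FALSE gives
#'   the Welch test.
#' @return Tibble, one row per stage: `stage`, `n_wt`, `n_mut`, `mean_wt`,
#'   `mean_mut`, `t`, `p`, `label`.
#' @export
compare_fish_groups <- function(measurements, stage = NULL,
                                var_equal = TRUE) {
  m <- relative_intensity(measurements)
  stages <- if (is.null(stage)) {
    intersect(.FISH_STAGES, unique(m$stage))
  } else stage
  if (length(stages) == 0) stop("no stage groups to compare", call. = FALSE)
  rows <- lapply(stages, function(st) {
    sub <- m[m$stage == st, , drop = FALSE]
    wt <- sub$ratio[sub$genotype == "WT"]
    mut <- sub$ratio[sub$genotype == "ISWI"]
    if (length(wt) < 2 || length(mut) < 2) {
      stop("stage ", st, ": each genotype needs >= 2 embryos",
           call. = FALSE)
    }
    if (stats::sd(wt) == 0 && stats::sd(mut) == 0) {
      if (mean(wt) == mean(mut)) {
        warning("stage ", st,
                ": both groups constant and equal; reporting NS.")
        return(tibble::tibble(stage = st, n_wt = length(wt),
                              n_mut = length(mut), mean_wt = mean(wt),
                              mean_mut = mean(mut), t = 0, p = 1,
                              label = "NS."))
      }
      # constant but different: infinitely strong separation
      return(tibble::tibble(stage = st, n_wt = length(wt),
                            n_mut = length(mut), mean_wt = mean(wt),
                            mean_mut = mean(mut),
                            t = sign(mean(mut) - mean(wt)) * Inf, p = 0,
                            label = "***"))
    }
    tt <- stats::t.test(mut, wt, var.equal = var_equal)
    tibble::tibble(stage = st, n_wt = length(wt), n_mut = length(mut),
                   mean_wt = mean(wt), mean_mut = mean(mut),
                   t = unname(tt$statistic), p = tt$p.value,
                   label = significance_label(tt$p.value))
  })
  dplyr::bind_rows(rows)
}
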