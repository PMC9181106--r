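# A self-contained two-group differential-expression stage: normalized
# group means, method-of-moments negative-binomial dispersion, a Wald test
# on log2 fold change, and Benjamini-Hochberg adjustment. This is a
# transparent NB-Wald test, deliberately simpler than shrinkage-based DE
# frameworks; externally computed DE tables in the same schema can be
# ingested in its place.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald differential-expression test
#'
#' For one sex, tests each transcript for a mutant/WT expression difference:
#' counts are normalized by median-of-ratios size factors computed on that
#' sex's samples; the log2 fold change is the ratio of normalized group
#' means; a per-transcript NB dispersion is estimated by the method of
#' moments (pooled over both groups, floored at `dispersion_floor`); the
#' Wald statistic is log2FC / SE with the delta-method standard error under
#' the NB variance model, referred to the standard normal (two-sided).
#' P-values are BH-adjusted over the tested transcripts.
#'
#' Transcripts with zero counts in every sample are excluded before testing
#' (reported via the `n_excluded` attribute). A group mean of zero with a
#' non-zero counterpart is floored at 0.5 normalized counts for the fold
#' change and SE so the statistic stays finite.
#'
#' @param counts A [count_matrix()].
#' @param sex `"F"` or `"M"`; only that sex's samples are used.
#' @param alpha Adjusted-p significance threshold for the `call` column
#'   (default 0.05; no fold-change cutoff is applied).
#' @param dispersion_floor Lower bound on the moment dispersion estimate.
#' @return A tibble of class `de_result`: `transcript_id`, `base_mean`,
#'   `mean_wt`, `mean_mut`, `log2_fc`, `stat`, `p`, `padj`, `call`
#'   (`up`, `down`, `ns`). Attributes: `sex`, `alpha`, `n_excluded`.
#' @export
de_test <- function(counts, sex, alpha = 0.05, dispersion_floor = 1e-8) {
  stopifnot(inherits(counts, "count_matrix"))
  samples <- counts$samples
  sel <- samples$sex == sex
  if (!any(sel)) stop("no samples for sex ", sex, call. = FALSE)
  sub <- counts$counts[, sel, drop = FALSE]
  sub_samples <- samples[sel, , drop = FALSE]
  n_wt <- sum(sub_samples$genotype == "WT")
  n_mut <- sum(sub_samples$genotype == "ISWI")
  if (n_wt < 2 || n_mut < 2) {
    stop("need >= 2 replicates per genotype group (have WT=", n_wt,
         ", ISWI=", n_mut, ")", call. = FALSE)
  }

  nonzero <- rowSums(sub) > 0
  n_excluded <- sum(!nonzero)
  sub <- sub[nonzero, , drop = FALSE]

  sf <- size_factors(count_matrix(sub, sub_samples))
  norm <- sweep(sub, 2, sf, "/")
  wt_cols <- sub_samples$genotype == "WT"
  mut_cols <- sub_samples$genotype == "ISWI"
  mu_wt <- rowMeans(norm[, wt_cols, drop = FALSE])
  mu_mut <- rowMeans(norm[, mut_cols, drop = FALSE])
  v_wt <- apply(norm[, wt_cols, drop = FALSE], 1, stats::var)
  v_mut <- apply(norm[, mut_cols, drop = FALSE], 1, stats::var)

  # moment estimate of NB dispersion alpha: var = mu + alpha mu^2, pooled
  disp_of <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, 0)
  disp <- pmax((disp_of(v_wt, mu_wt) + disp_of(v_mut, mu_mut)) / 2,
               dispersion_floor)

  mu_wt_f <- pmax(mu_wt, 0.5)
  mu_mut_f <- pmax(mu_mut, 0.5)
  log2_fc <- log2(mu_mut_f / mu_wt_f)
  # delta method on log2 of a group mean: Var = (mu + a mu^2) / (n mu^2 ln2^2)
  se2 <- ((mu_wt_f + disp * mu_wt_f^2) / (n_wt * mu_wt_f^2) +
            (mu_mut_f + disp * mu_mut_f^2) / (n_mut * mu_mut_f^2)) /
    log(2)^2
  stat <- log2_fc / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(stat))
  padj <- bh_adjust(p)

  res <- tibble::tibble(
    transcript_id = rownames(sub),
    base_mean = unname(rowMeans(norm)),
    mean_wt = unname(mu_wt),
    mean_mut = unname(mu_mut),
    log2_fc = unname(log2_fc),
    stat = unname(stat),
    p = unname(p),
    padj = unname(padj),
    call = dplyr::case_when(
      padj < alpha & log2_fc > 0 ~ "up",
      padj < alpha & log2_fc < 0 ~ "down",
      TRUE ~ "ns"
    )
  )
  class(res) <- c("de_result", class(res))
  attr(res, "sex") <- sex
  attr(res, "alpha") <- alpha
  attr(res, "n_excluded") <- n_excluded
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> sex %s, alpha %.3g: %d up, %d down, %d ns (%d all-zero excluded)\n",
              attr(x, "sex"), attr(x, "alpha"),
              sum(x$call == "up"), sum(x$call == "down"),
              sum(x$call == "ns"), attr(x, "n_excluded")))
  NextMethod()
}

#' @rdname de_test
#' @param x A `de_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  tibble::tibble(
    sex = attr(x, "sex"),
    alpha = attr(x, "alpha"),
    n_tested = nrow(x),
    n_excluded = attr(x, "n_excluded"),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down")
  )
}

#' Sex-concordance sets of differentially expressed transcripts
#'
#' Intersects the per-sex up/down calls over the shared transcript
#' universe: reports Venn-style counts (up in females only, males only,
#' both; likewise for down) and partitions the transcripts DE in both
#' sexes into the four trend categories: both up, both down, up in
#' females / down in males, down in females / up in males.
#'
#' @param de_female,de_male `de_result` tibbles (or any tibbles with
#'   `transcript_id` and `call` columns) for the two sexes.
#' @return An object of class `concordance_sets`: list with `categories`
#'   (tibble `transcript_id`, `category` over the both-sex DE
#'   intersection), `venn` (tibble `direction`, `female_only`,
#'   `male_only`, `both`) and `counts` (named category counts).
#' @export
concordance <- function(de_female, de_male) {
  for (d in list(de_female, de_male)) {
    if (anyDuplicated(d$transcript_id) > 0) {
      stop("duplicate transcript calls in a DE table: ",
           paste(unique(d$transcript_id[duplicated(d$transcript_id)]),
                 collapse = ", "), call. = FALSE)
    }
  }
  up_f <- de_female$transcript_id[de_female$call == "up"]
  down_f <- de_female$transcript_id[de_female$call == "down"]
  up_m <- de_male$transcript_id[de_male$call == "up"]
  down_m <- de_male$transcript_id[de_male$call == "down"]

  de_f <- c(up_f, down_f)
  de_m <- c(up_m, down_m)
  both <- intersect(de_f, de_m)
  category <- dplyr::case_when(
    both %in% up_f & both %in% up_m ~ "both_up",
    both %in% down_f & both %in% down_m ~ "both_down",
    both %in% up_f & both %in% down_m ~ "F_up_M_down",
    TRUE ~ "F_down_M_up"
  )
  categories <- tibble::tibble(transcript_id = both,
                               category = category) |>
    dplyr::arrange(.data$transcript_id)
  venn <- tibble::tibble(
    direction = c("up", "down"),
    female_only = c(length(setdiff(up_f, de_m)),
                    length(setdiff(down_f, de_m))),
    male_only = c(length(setdiff(up_m, de_f)),
                  length(setdiff(down_m, de_f))),
    both = c(length(intersect(up_f, up_m)),
             length(intersect(down_f, down_m)))
  )
  counts <- vapply(c("both_up", "both_down", "F_up_M_down", "F_down_M_up"),
                   function(k) sum(category == k), integer(1))
  structure(list(categories = categories, venn = venn, counts = counts),
            class = "concordance_sets")
}

#' @export
print.concordance_sets <- function(x, ...) {
  cat(sprintf("<concordance_sets> %d transcript(s) DE in both sexes\n",
              nrow(x$categories)))
  cat(paste(sprintf("  %s: %d", names(x$counts), x$counts),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname concordance
#' @param x A `concordance_sets`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.concordance_sets <- function(x, ...) x$categories
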