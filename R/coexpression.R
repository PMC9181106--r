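# lncRNA-mRNA co-expression screening: all-pairs Pearson correlation over
# normalized counts, thresholded on |r| (or signed r) and p, plus
# connection-degree ranking of the resulting network.

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson r and the two-sided p-value from
#' t = r sqrt((n-2) / (1-r^2)) on n-2 degrees of freedom; |r| = 1 maps to
#' p = 0.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return Tibble: `r`, `p`, `n`.
#' @export
pearson_pair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, p = p, n = n)
}

#' Screen all lncRNA-mRNA pairs for co-expression
#'
#' Tests every lncRNA x mRNA pair by Pearson correlation across the shared
#' sample columns and keeps pairs passing the threshold rule:
#' `|r| > r_min` in `"absolute"` mode (the default — negative edges are
#' biologically meaningful and displayed in co-expression networks) or
#' `r > r_min` in `"signed"` mode, and `p < p_max` in either mode.
#'
#' @param lnc_matrix,mrna_matrix Normalized expression matrices
#'   (transcripts x samples) with identical sample columns; rownames are
#'   ids.
#' @param r_min Correlation threshold (default 0.95, strict).
#' @param p_max P-value threshold (default 0.05, strict).
#' @param mode `"absolute"` or `"signed"`.
#' @return Tibble of edges sorted by (lncRNA_id, mRNA_id): `lncRNA_id`,
#'   `mRNA_id`, `r`, `p`, `sign` (`"positive"` or `"negative"`).
#' @export
screen_pairs <- function(lnc_matrix, mrna_matrix, r_min = 0.95,
                         p_max = 0.05, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  lnc_matrix <- as.matrix(lnc_matrix)
  mrna_matrix <- as.matrix(mrna_matrix)
  if (ncol(lnc_matrix) != ncol(mrna_matrix) ||
      !identical(colnames(lnc_matrix), colnames(mrna_matrix))) {
    stop("matrices must share identical sample columns", call. = FALSE)
  }
  n <- ncol(lnc_matrix)
  if (n < 3) stop("need >= 3 samples", call. = FALSE)

  keep_var <- function(m) apply(m, 1, stats::sd) > 0
  lnc_ok <- keep_var(lnc_matrix)
  mrna_ok <- keep_var(mrna_matrix)
  lnc_matrix <- lnc_matrix[lnc_ok, , drop = FALSE]
  mrna_matrix <- mrna_matrix[mrna_ok, , drop = FALSE]
  if (nrow(lnc_matrix) == 0 || nrow(mrna_matrix) == 0) {
    return(tibble::tibble(lncRNA_id = character(), mRNA_id = character(),
                          r = double(), p = double(), sign = character()))
  }

  r_mat <- stats::cor(t(lnc_matrix), t(mrna_matrix))
  r_clip <- pmin(pmax(r_mat, -1), 1)
  p_mat <- ifelse(abs(r_clip) >= 1, 0,
                  2 * stats::pt(-abs(r_clip * sqrt((n - 2) /
                                                     (1 - r_clip^2))),
                                df = n - 2))
  pass <- if (mode == "absolute") abs(r_mat) > r_min else r_mat > r_min
  pass <- pass & p_mat < p_max
  idx <- which(pass, arr.ind = TRUE)
  tibble::tibble(
    lncRNA_id = rownames(lnc_matrix)[idx[, 1]],
    mRNA_id = rownames(mrna_matrix)[idx[, 2]],
    r = r_mat[idx],
    p = p_mat[idx],
    sign = ifelse(r_mat[idx] >= 0, "positive", "negative")
  ) |>
    dplyr::arrange(.data$lncRNA_id, .data$mRNA_id)
}

#' Connection degree per network node, ranked
#'
#' Degree = number of incident edges; nodes are ranked descending with a
#' deterministic alphabetical tie-break. Genes with many co-expressed
#' lncRNAs (high connectivity) rank first.
#'
#' @param edges Edge tibble from [screen_pairs()].
#' @return Tibble: `node`, `side` (`lncRNA`/`mRNA`), `degree`, `rank`.
#' @export
node_degrees <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble::tibble(node = character(), side = character(),
                          degree = integer(), rank = integer()))
  }
  dplyr::bind_rows(
    tibble::tibble(node = edges$lncRNA_id, side = "lncRNA"),
    tibble::tibble(node = edges$mRNA_id, side = "mRNA")
  ) |>
    dplyr::count(.data$node, .data$side, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node) |>
    dplyr::mutate(rank = dplyr::row_number())
}
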