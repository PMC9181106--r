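norm_fixture <- function(mat, genotype, sex = "F", factors = NULL) {
  cm <- toy_count_matrix(mat, genotype, sex)
  normalize_counts(cm, factors = factors)
}

test_that("the dosage reference lines are log2(3/2) and symmetric", {
  f <- dosage_frame()
  pos <- f$log2_ratio[f$line == "positive_dosage"]
  inv <- f$log2_ratio[f$line == "inverse_dosage"]
  expect_equal(round(pos, 2), 0.58)
  expect_equal(pos, -inv)
  expect_equal(f$log2_ratio[f$line == "compensation"], 0)
  expect_equal(pos, log2(1.5))
})

test_that("median-of-ratios size factors match the hand computation", {
  mat <- matrix(c(2L, 4L, 8L, 16L), nrow = 2, byrow = TRUE,
                dimnames = list(c("t1", "t2"), c("s1", "s2")))
  sf <- size_factors(mat)
  # geometric means are sqrt(8) and sqrt(128); every ratio is 1/sqrt(2) in
  # s1 and sqrt(2) in s2
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(round(unname(sf), 4), c(0.7071, 1.4142))

  ident <- matrix(5L, 3, 3, dimnames = list(paste0("t", 1:3),
                                            paste0("s", 1:3)))
  expect_equal(unname(size_factors(ident)), rep(1, 3))

  # multiplying one column by k multiplies its factor by k, up to the
  # common geometric constant the method leaves free
  mat2 <- mat
  mat2[, 2] <- mat2[, 2] * 3L
  sf1 <- size_factors(mat); sf2 <- size_factors(mat2)
  expect_equal(sf2[[2]] / sf2[[1]], 3 * sf1[[2]] / sf1[[1]],
               tolerance = 1e-12)
})

test_that("size factors agree with the established implementation", {
  set.seed(8)
  mat <- matrix(rnbinom(600, mu = 200, size = 20), 100, 6,
                dimnames = list(sprintf("t%03d", 1:100), paste0("s", 1:6)))
  ours <- size_factors(mat)
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("size factors recover exact column multiples and error on sparse input", {
  base <- matrix(rpois(300, 100) + 1L, 100, 3)
  mat <- cbind(base[, 1], base[, 1] * 2L, base[, 1] * 4L)
  dimnames(mat) <- list(sprintf("t%03d", 1:100), paste0("s", 1:3))
  sf <- size_factors(mat)
  expect_equal(unname(sf / sf[1]), c(1, 2, 4), tolerance = 1e-12)

  sparse <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(sparse), "all-positive")
})

test_that("normalization divides by factors and defines baseMean", {
  mat <- matrix(500L, 2, 4, dimnames = list(c("t1", "t2"), paste0("s", 1:4)))
  n <- norm_fixture(mat, c("WT", "WT", "ISWI", "ISWI"),
                    factors = rep(1, 4))
  expect_equal(n$normalized, mat + 0)
  expect_equal(n$base_mean$base_mean, c(500, 500))
  # baseMean invariant under joint rescaling of counts and factors
  n2 <- norm_fixture(mat * 2L, c("WT", "WT", "ISWI", "ISWI"),
                     factors = rep(2, 4))
  expect_equal(n2$base_mean, n$base_mean)
})

test_that("log2 ratios hit the textbook values and respect the floor", {
  mat <- matrix(as.integer(c(2, 2, 4, 4,      # ratio 2 -> log2 1
                             10, 10, 10, 10,  # ratio 1 -> 0
                             2, 2, 3, 3,      # ratio 3/2 -> 0.58
                             0, 0, 50, 50)),  # WT below floor -> excluded
                nrow = 4, byrow = TRUE,
                dimnames = list(c("a", "b", "c", "d"), paste0("s", 1:4)))
  chroms <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                           chromosome = c("X", "2L", "3R", "2R"))
  n <- norm_fixture(mat, c("WT", "WT", "ISWI", "ISWI"), factors = rep(1, 4))
  rec <- group_log2_ratios(n, sex = "F", chromosomes = chroms)
  expect_equal(rec$log2_ratio[rec$transcript_id == "a"], 1)
  expect_equal(rec$log2_ratio[rec$transcript_id == "b"], 0)
  expect_equal(round(rec$log2_ratio[rec$transcript_id == "c"], 2), 0.58)
  expect_false("d" %in% rec$transcript_id)
  expect_equal(rec$stratum[rec$transcript_id == "a"], "X")
  expect_equal(rec$stratum[rec$transcript_id == "b"], "autosome")
})

test_that("swapping genotype labels negates ratios and medians", {
  set.seed(10)
  mat <- matrix(rnbinom(80 * 6, mu = 300, size = 20), 80, 6,
                dimnames = list(sprintf("t%02d", 1:80), paste0("s", 1:6)))
  chroms <- tibble::tibble(transcript_id = rownames(mat),
                           chromosome = rep(c("X", "2L"), 40))
  g <- c("WT", "WT", "WT", "ISWI", "ISWI", "ISWI")
  n1 <- norm_fixture(mat, g, factors = rep(1, 6))
  n2 <- norm_fixture(mat, rev(g), factors = rep(1, 6))
  r1 <- group_log2_ratios(n1, "F", chromosomes = chroms)
  r2 <- group_log2_ratios(n2, "F", chromosomes = chroms)
  expect_equal(r1$log2_ratio, -r2$log2_ratio)
  m1 <- median_by_stratum(r1)
  m2 <- median_by_stratum(r2)
  expect_equal(m1$median_log2_ratio, -m2$median_log2_ratio)
})

test_that("ratio histograms normalize correctly", {
  rec <- tibble::tibble(transcript_id = c("a", "b", "c"), class = "mRNA",
                        stratum = "X", mean_wt = 1, mean_mut = 1,
                        log2_ratio = c(0, 0, 1.0))
  h <- ratio_histogram(rec, bin_width = 0.5)
  hh <- h$histogram
  expect_equal(hh$frequency[hh$bin_start == 0], 2 / 3)
  expect_equal(hh$frequency[hh$bin_start == 1], 1 / 3)
  expect_equal(sum(hh$frequency), 1)
  expect_equal(h$out_of_range$n, 0L)
  expect_error(ratio_histogram(rec, bin_width = 0), "bin_width")
  # records outside the range carry their mass to out_of_range
  rec2 <- dplyr::mutate(rec, log2_ratio = c(0, 5, -4))
  h2 <- ratio_histogram(rec2)
  expect_equal(h2$out_of_range$n, 2L)
  expect_equal(sum(h2$histogram$frequency), 1 / 3)
})

test_that("a planted shift shows up as the modal histogram bin", {
  set.seed(20)
  rec <- tibble::tibble(transcript_id = sprintf("t%04d", 1:1000),
                        class = "lncRNA", stratum = "X", mean_wt = 1,
                        mean_mut = 1, log2_ratio = rnorm(1000, 1.0, 0.2))
  hh <- ratio_histogram(rec)$histogram
  modal <- hh$bin_mid[which.max(hh$frequency)]
  expect_lt(abs(modal - 1.0), 0.1 + 1e-9)
})

test_that("stratified medians recover planted per-class shifts", {
  set.seed(30)
  n <- 500
  rec <- dplyr::bind_rows(
    tibble::tibble(transcript_id = sprintf("l%04d", 1:n), class = "lincRNA",
                   stratum = "autosome", mean_wt = 1, mean_mut = 1,
                   log2_ratio = rnorm(n, 0.4, 0.3)),
    tibble::tibble(transcript_id = sprintf("i%04d", 1:n),
                   class = "intronic", stratum = "autosome", mean_wt = 1,
                   mean_mut = 1, log2_ratio = rnorm(n, -0.2, 0.3)))
  m <- median_by_stratum(rec)
  expect_lt(abs(m$median_log2_ratio[m$class == "lincRNA"] - 0.4), 0.05)
  expect_lt(abs(m$median_log2_ratio[m$class == "intronic"] + 0.2), 0.05)
  # simple cases and the subset path
  rec3 <- tibble::tibble(transcript_id = c("a", "b", "c"), class = "mRNA",
                         stratum = "X", mean_wt = 1, mean_mut = 1,
                         log2_ratio = c(-1, 0, 1))
  expect_equal(median_by_stratum(rec3)$median_log2_ratio, 0)
  sub <- median_by_stratum(rec3, subset = c("a", "b"))
  expect_equal(sub$median_log2_ratio, -0.5)
  expect_equal(sub$n, 2L)
  expect_warning(median_by_stratum(rec3, subset = "zzz"), "omitted")
})

test_that("distribution comparison behaves at its extremes and under separation", {
  x <- c(0.1, 0.5, 0.2, 0.8, 0.3)
  same <- compare_distributions(x, x)
  expect_equal(same$statistic, 0)
  disj <- compare_distributions(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disj$statistic, 1)
  set.seed(40)
  sep <- compare_distributions(rnorm(200, 0, 0.3), rnorm(200, 0.5, 0.3))
  expect_lt(sep$p_value, 0.01)
  expect_error(compare_distributions(1, c(1, 2)), "size >= 2")
})
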