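test_that("reading a CSV coerces blanks and sentinels to missing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("crisis,a,b", "SOM001,3,", "ETH001,2,4"), f)
  meta <- indicator_meta(c("a", "b"), pillar = "impact")
  tab <- read_indicator_table(f, meta)
  expect_equal(dim(tab$values), c(2L, 2L))
  expect_equal(sum(is.na(tab$values)), 1L)
  expect_identical(tab$crisis_ids, c("SOM001", "ETH001"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("crisis,a,b", "SOM001,N/A,x", "ETH001,2,4"), f2)
  expect_message(tab2 <- read_indicator_table(f2, meta), "non-numeric")
  expect_equal(sum(is.na(tab2$values)), 2L)
})

test_that("out-of-range values and unknown columns are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("crisis,a", "SOM001,7"), f)
  meta <- indicator_meta("a", pillar = "impact", scale_min = 0,
                         scale_max = 5)
  expect_error(read_indicator_table(f, meta), "outside scale")
  meta2 <- indicator_meta(c("a", "zz"), pillar = "impact")
  expect_error(read_indicator_table(f, meta2), "zz")
})

test_that("missingness screening applies a strict threshold", {
  set.seed(1)
  n <- 100
  v <- cbind(full = runif(n, 0, 5),
             m82 = ifelse(runif(n) < 0.82, NA, 3),
             m27 = ifelse(seq_len(n) <= 27, NA, 2),
             m25 = ifelse(seq_len(n) <= 25, NA, 2))
  tab <- make_table(v)
  res <- missingness_screen(tab, threshold = 0.25)
  expect_setequal(res$report$removed, c("m82", "m27"))
  expect_setequal(colnames(res$table$values), c("full", "m25"))
  expect_equal(unname(res$report$fractions[["m27"]]), 0.27)
})

test_that("screening removes exactly the indicators above threshold (property)", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    p <- sample(3:8, 1)
    v <- matrix(sample(0:5, n * p, replace = TRUE), n, p)
    rates <- runif(p, 0, 0.6)
    for (j in seq_len(p)) v[runif(n) < rates[j], j] <- NA
    tab <- make_table(v)
    thr <- runif(1, 0.1, 0.5)
    res <- missingness_screen(tab, thr)
    brute <- colnames(v <- tab$values)[
      sapply(seq_len(p), function(j) sum(is.na(v[, j])) / n > thr)]
    expect_setequal(res$report$removed, brute)
  }
})

test_that("median imputation fills with the column median and nothing else", {
  tab <- make_table(cbind(a = c(2, NA, 4, 4), b = c(1, 3, NA, NA),
                          c = c(0, 1, 2, 3)))
  imp <- impute_median(tab)
  expect_equal(unname(imp$values[2, "a"]), 4)
  expect_equal(unname(imp$values[3:4, "b"]), c(2, 2))
  expect_equal(imp$values[, "c"], tab$values[, "c"])
  obs <- !is.na(tab$values)
  expect_equal(imp$values[obs], tab$values[obs])
  # column medians unchanged by imputation
  for (j in 1:3) {
    expect_equal(median(imp$values[, j]),
                 median(tab$values[, j], na.rm = TRUE))
  }
  expect_error(impute_median(make_table(cbind(a = c(NA, NA)))),
               "no observed")
})

test_that("standardization gives z-scores over observed cells only", {
  tab <- make_table(cbind(a = c(0, 2), b = c(1, 4)), scale_min = 0)
  z <- standardize_indicators(tab)
  expect_equal(unname(z$values[, "a"]), c(-1, 1) / sqrt(2))

  set.seed(3)
  v <- matrix(runif(200, 0, 5), 40, 5)
  v[sample(200, 30)] <- NA
  z2 <- standardize_indicators(make_table(v))
  for (j in 1:5) {
    col <- z2$values[, j][!is.na(z2$values[, j])]
    expect_lt(abs(mean(col)), 1e-8)
    expect_lt(abs(sd(col) - 1), 1e-8)
  }
  # idempotence
  z3 <- standardize_indicators(
    indicator_table(z2$values,
                    indicator_meta(colnames(z2$values), "impact",
                                   scale_min = -1e6, scale_max = 1e6)))
  expect_lt(max(abs(z3$values - z2$values), na.rm = TRUE), 1e-8)
  expect_error(standardize_indicators(make_table(cbind(a = c(2, 2, 2)))),
               "constant")
})

test_that("correlations are pairwise-complete and match a brute-force loop", {
  set.seed(8)
  v <- matrix(runif(240, 0, 5), 40, 6)
  v[sample(240, 40)] <- NA
  tab <- make_table(v)
  r <- indicator_correlations(tab, method = "pearson")
  expect_equal(unname(r), brute_cor(tab$values), tolerance = 1e-12)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 6))

  # Spearman is invariant under strictly monotone transforms
  rs1 <- indicator_correlations(tab, method = "spearman")
  v2 <- v; v2[, 1] <- exp(v2[, 1])
  rs2 <- indicator_correlations(make_table(v2, scale_min = 0,
                                           scale_max = 1e6),
                                method = "spearman")
  expect_equal(rs1[1, 2], rs2[1, 2], tolerance = 1e-12)

  # entries with < 3 complete pairs are flagged missing
  v3 <- cbind(a = c(1, 2, NA, NA, 3), b = c(NA, NA, 1, 2, NA),
              c = 1:5)
  r3 <- indicator_correlations(make_table(v3), method = "pearson")
  expect_true(is.na(r3["a", "b"]))
  expect_false(is.na(r3["a", "c"]))
})

test_that("fraction of |r|>0.6 pairs matches a brute-force count", {
  x <- two_block_data(n = 500)
  r <- indicator_correlations(make_table(x, scale_min = -10,
                                         scale_max = 10),
                              method = "pearson")
  lo <- r[lower.tri(r)]
  expect_equal(high_correlation_fraction(r, 0.6),
               sum(abs(lo) > 0.6) / length(lo))
})

test_that("descriptives use observed values only", {
  tab <- make_table(cbind(a = c(1, 2, 3), b = c(NA, NA, NA)))
  d <- describe_indicators(tab)
  expect_equal(d$mean[1], 2)
  expect_equal(d$median[1], 2)
  expect_equal(d$n[1], 3L)
  expect_equal(d$n[2], 0L)
  expect_true(is.na(d$mean[2]))
})
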