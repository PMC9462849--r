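test_that("paired t-test matches the closed-form t on clean differences", {
  x <- c(1, 2, 3, 4); y <- rep(0, 4)
  res <- paired_t(x, y)
  d <- x - y
  t_expected <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$statistic, t_expected, tolerance = 1e-12)
  expect_equal(res$statistic, 3.873, tolerance = 1e-3)
  expect_equal(res$p_value, 2 * pt(-t_expected, df = 3), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0305, tolerance = 1e-2)

  sym <- paired_t(c(-2, -1, 1, 2), rep(0, 4))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "degenerate")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("paired t-test is equivariant under common affine transforms", {
  set.seed(61)
  x <- rnorm(8); y <- rnorm(8)
  a <- paired_t(x, y)
  b <- paired_t(3 * x + 2, 3 * y + 2)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
})

test_that("signed-rank exact p matches known extremes", {
  res <- wilcoxon_signed_rank(1:6, rep(0, 6))
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64)
  expect_identical(res$method_path, "exact-enumeration")

  one <- wilcoxon_signed_rank(5, 3)
  expect_equal(one$p_value, 1)

  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("signed-rank exact path equals literal enumeration for n <= 8", {
  set.seed(62)
  for (n in 2:8) {
    for (rep in 1:3) {
      d <- round(rnorm(n), 1)           # rounding produces ties in |d|
      d <- d[d != 0]
      if (length(d) < 2) next
      res <- wilcoxon_signed_rank(d, rep(0, length(d)))
      expect_equal(res$p_value, brute_signed_rank_p(d),
                   info = paste("n =", n, "rep", rep))
    }
  }
})

test_that("signed-rank exact path agrees with wilcox.test on untied data", {
  set.seed(63)
  for (n in c(5, 9, 14)) {
    x <- rnorm(n); y <- rnorm(n)
    res <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank approximation is close to exact and engages at n > 25", {
  set.seed(64)
  x <- rnorm(15, mean = 0.8); y <- rnorm(15)
  exact <- wilcoxon_signed_rank(x, y)
  approx <- wilcoxon_signed_rank(x, y, exact_max = 0L)
  expect_identical(approx$method_path, "normal-approximation")
  expect_lt(abs(approx$p_value - exact$p_value),
            0.1 * max(exact$p_value, 0.05))

  big <- wilcoxon_signed_rank(rnorm(26, 0.5), rnorm(26))
  expect_identical(big$method_path, "normal-approximation")
})

test_that("zero differences are dropped and logged", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 4), c(1, 1, 1, 1, 1))
  expect_equal(res$n, 4)
  expect_match(res$note, "1 zero difference")
})

test_that("Mann-Whitney exact p matches known extremes and enumeration", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_identical(res$method_path, "exact-enumeration")

  set.seed(65)
  for (n1 in 1:4) for (n2 in 1:4) {
    x <- rnorm(n1); y <- rnorm(n2)
    res <- mann_whitney(x, y)
    expect_equal(res$p_value, brute_mann_whitney_p(x, y),
                 info = paste(n1, n2))
  }
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test and handles ties", {
  set.seed(66)
  x <- rnorm(6); y <- rnorm(7)
  res <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  tied <- mann_whitney(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_match(tied$method_path, "ties")
  ref_t <- suppressWarnings(wilcox.test(c(1, 2, 2, 3), c(2, 3, 3, 4),
                                        correct = TRUE))
  expect_equal(tied$p_value, ref_t$p.value, tolerance = 1e-9)
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(67)
  x <- rlnorm(9); y <- rlnorm(9)
  a <- mann_whitney(x, y); b <- mann_whitney(log(x), log(y))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, b$statistic)
  # signed-rank: invariant to a common positive scaling of the pairs
  c1 <- wilcoxon_signed_rank(x, y)
  c2 <- wilcoxon_signed_rank(5 * x, 5 * y)
  expect_equal(c1$p_value, c2$p_value)
})

test_that("Mann-Whitney p falls monotonically with increasing shift", {
  set.seed(68)
  x <- rnorm(8); y <- rnorm(8)
  ps <- vapply(c(0, 0.8, 1.6, 3), function(sh)
    mann_whitney(x + sh, y)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

toy_records <- function(mi_a, mi_b, region_b = "CI-R") {
  rbind(
    data.frame(disc_id = paste0("d", seq_along(mi_a)), condition = "ctr",
               region = "P", subregion = "column", n_pixels = 100,
               integrated_density = mi_a * 100, mean_intensity = mi_a,
               relative_intensity = 1),
    data.frame(disc_id = paste0("d", seq_along(mi_b)), condition = "ctr",
               region = region_b, subregion = "column", n_pixels = 100,
               integrated_density = mi_b * 100, mean_intensity = mi_b,
               relative_intensity = 1))
}

test_that("fold change and percent reduction follow their definitions", {
  rec <- toy_records(c(10, 12, 14), c(10, 12, 14))
  expect_equal(fold_change(rec, "P", "CI-R"), 1.0)
  rec2 <- toy_records(2 * c(10, 12, 14), c(10, 12, 14))
  expect_equal(fold_change(rec2, "P", "CI-R"), 2.0)

  t0 <- toy_records(c(10, 12, 14), c(10, 12, 14))
  expect_equal(percent_reduction(t0, t0, "P"), 0)
  chase <- toy_records(c(5, 6, 7), c(5, 6, 7))
  expect_equal(percent_reduction(t0, chase, "P"), 50)
  zero <- toy_records(c(0, 0), c(0, 0))
  expect_warning(pr <- percent_reduction(zero, chase, "P"),
                 "not positive")
  expect_true(is.na(pr))
})

test_that("report output is deterministic with a documented schema", {
  rec <- toy_records(c(10, 12, 14, 13), c(9, 11, 12, 10))
  comp <- compare_cohorts(rec, rec, regions = c("P", "CI-R"),
                          subregions = "column")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- report_results(rec, comp, d1)
  f2 <- report_results(rec, comp, d2)
  expect_identical(readLines(f1[["comparisons"]]),
                   readLines(f2[["comparisons"]]))
  got <- read.csv(f1[["comparisons"]])
  expect_true(all(c("test", "statistic", "p_value", "n", "n_a", "n_b",
                    "effect", "method_path", "measure", "group_a",
                    "group_b", "subregion") %in% names(got)))
  # no comparisons: records table and log only
  f3 <- report_results(rec, NULL, withr::local_tempdir())
  expect_setequal(names(f3), c("records", "log"))
})
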