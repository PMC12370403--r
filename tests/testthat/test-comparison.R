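test_that("percent differences reproduce the published comparison cells", {
  # range vs equation, denominator = equation value
  # within half a printing unit of each published cell; the CC 100-mm cell
  # computes to 8.14% from the rounded table inputs while the report prints
  # 8.2% (unrounded intermediates), hence its slightly wider band
  expect_lt(abs(percent_diff(1.55, 1.45) - 6.9), 0.05)
  expect_lt(abs(percent_diff(2.15, 1.96) - 9.7), 0.05)
  expect_lt(abs(percent_diff(2.37, 2.58) - 8.2), 0.1)
  expect_lt(abs(percent_diff(1.77, 1.59) - 11), 0.5)
  expect_lt(abs(percent_diff(2.38, 2.24) - 6.3), 0.0501)
  expect_lt(abs(percent_diff(3.03, 4.72) - 35.8), 0.05)
  expect_equal(percent_diff(1.3, 1.3), 0)
  expect_error(percent_diff(1, 0), "positive")
})

test_that("simplest-approach ratios use the simplest DRL as denominator", {
  expect_equal(round(compare_to_simplest(2.37, 1.49)), 59)
  expect_equal(round(compare_to_simplest(3.03, 1.69)), 79)
  expect_equal(round(compare_to_simplest(2.58, 1.49)), 73)
  expect_equal(round(compare_to_simplest(4.72, 1.69)), 179)
  expect_equal(compare_to_simplest(1.49, 1.49), 0)
})

test_that("signed-rank test matches hand-derived exact cases", {
  r <- signed_rank_test(1:6)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 64)  # only one sign pattern is as extreme
  expect_equal(r$n_pairs, 6L)
  # perfectly antisymmetric differences with ties: p = 1 by symmetry
  r2 <- signed_rank_test(c(-1, 1, -2, 2, -3, 3))
  expect_equal(r2$p_value, 1)
  expect_equal(r2$w_plus, 1.5 + 3.5 + 5.5)
  # flipping every sign leaves the two-sided p unchanged
  set.seed(4)
  d <- sample(c(-5:-1, 1:7), 9)
  expect_equal(signed_rank_test(d)$p_value, signed_rank_test(-d)$p_value)
  # zeros are dropped before ranking
  expect_equal(signed_rank_test(c(0, 0, 1:6))$n_pairs, 6L)
  # all-zero differences are degenerate, reported with p = 1
  r0 <- signed_rank_test(rep(0, 10))
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$n_pairs, 0L)
})

test_that("exact signed-rank p-values agree with full sign enumeration", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(-6:6, n, replace = TRUE)
    d <- d[d != 0]
    if (length(d) < 2) next
    got <- signed_rank_test(d)
    expect_equal(got$p_value, enumerate_signed_rank_p(d),
                 tolerance = 1e-12,
                 label = paste("diffs:", paste(d, collapse = ",")))
  }
})

test_that("exact signed-rank p-values agree with wilcox.test when tie-free", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    d <- sample(seq(-30, 30)[-31], n)  # distinct magnitudes likely
    d <- d[!duplicated(abs(d)) & d != 0]
    if (length(d) < 6) next
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(signed_rank_test(d)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("large-n signed-rank approximation tracks wilcox.test", {
  set.seed(8)
  d <- round(rnorm(60, 0.4, 1), 2)
  d <- d[d != 0]
  got <- signed_rank_test(d)$p_value
  ref <- stats::wilcox.test(d, correct = TRUE)$p.value
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("equation-vs-range comparison populates the grid correctly", {
  g <- generate_cohort(synth_config(n_centers = 6,
                                    exams_per_center = rep(150, 6),
                                    contamination = 0, seed = 19))
  fl <- apply_exclusions(g$cohort)
  b <- binned_drl_table(fl$cohort, "CC")
  fa <- fit_all(b, seed = 19)
  s <- simplest_drl(fl$cohort, "CC")
  comp <- compare_equation_vs_ranges(fa$curve, b, simplest = s)
  grid <- comp$grid
  expect_equal(grid$cbt, 20:100)
  # grid point 50 takes the DRL of the [50, 60) bin
  expect_equal(grid$range_drl[grid$cbt == 50], b$drl[b$bin_lo == 50])
  expect_equal(grid$range_drl[grid$cbt == 100], b$drl[b$bin_lo == 90])
  # the invariant defining the difference columns
  expect_equal(grid$pct_diff_range,
               abs(grid$range_drl - grid$eq_drl) / grid$eq_drl * 100)
  expect_equal(grid$pct_diff_simplest,
               abs(grid$eq_drl - s) / s * 100)
  expect_equal(comp$wilcoxon$n_pairs,
               sum(grid$range_drl[!is.na(grid$range_drl)] !=
                     grid$eq_drl[!is.na(grid$range_drl)]))
})

test_that("a step function equal to the curve gives zero diffs, p = 1", {
  flat <- drl_curve(make_fit("linear", c(a = 1.5, b = 0)), "CC",
                    domain = c(20, 100))
  tab <- toy_cohort(list(a = rep(1.5, 3)), cbt = 55)
  b <- binned_drl_table(tab, "CC")
  b$drl[] <- as.numeric(evaluate_curve(flat, b$representative_cbt))
  b$empty[] <- FALSE
  comp <- compare_equation_vs_ranges(flat, b)
  expect_true(all(abs(comp$grid$pct_diff_range) < 1e-9))
  expect_true(comp$wilcoxon$degenerate)
  expect_equal(comp$wilcoxon$p_value, 1)
  expect_equal(comp$wilcoxon$n_pairs, 0L)
})

test_that("limit-curve classification respects boundary conventions", {
  lim <- limit_curves(
    acceptable = data.frame(cbt_mm = c(20, 100), mGy = c(2, 4)),
    achievable = data.frame(cbt_mm = c(20, 100), mGy = c(1, 2)))
  # constant curve below the achievable limit everywhere
  low <- drl_curve(make_fit("linear", c(a = 0.5, b = 0)), "CC", c(20, 100))
  cl <- classify_against_limits(low, lim)
  expect_true(all(cl$grid$class == "below_achievable"))
  expect_equal(nrow(cl$regions), 1L)
  # a rising line crossing the achievable limit once -> two regions
  rising <- drl_curve(make_fit("linear", c(a = 0.2, b = 0.02)), "CC",
                      c(20, 100))
  cl2 <- classify_against_limits(rising, lim)
  expect_equal(unique(cl2$grid$class), c("below_achievable", "between"))
  expect_equal(nrow(cl2$regions), 2L)
  # boundary inclusive downward: exactly on the acceptable limit -> between,
  # exactly on the achievable limit -> below_achievable
  lim_flat <- limit_curves(
    acceptable = data.frame(cbt_mm = c(20, 100), mGy = c(2, 2)),
    achievable = data.frame(cbt_mm = c(20, 100), mGy = c(1, 1)))
  const_curve <- function(v)
    drl_curve(make_fit("linear", c(a = v, b = 0)), "CC", c(20, 100))
  cl3 <- classify_against_limits(const_curve(2), lim_flat)
  expect_true(all(cl3$grid$class == "between"))
  cl3b <- classify_against_limits(const_curve(1), lim_flat)
  expect_true(all(cl3b$grid$class == "below_achievable"))
  # grid points beyond the limit tables are uncovered, not classified
  lim_short <- limit_curves(
    acceptable = data.frame(cbt_mm = c(30, 80), mGy = c(2, 4)),
    achievable = data.frame(cbt_mm = c(30, 80), mGy = c(1, 2)))
  cl4 <- classify_against_limits(low, lim_short)
  expect_true(all(cl4$grid$class[cl4$grid$cbt < 30] == "uncovered"))
  expect_true(all(cl4$grid$class[cl4$grid$cbt > 80] == "uncovered"))
  # achievable above acceptable is rejected outright
  expect_error(limit_curves(
    acceptable = data.frame(cbt_mm = c(20, 100), mGy = c(1, 2)),
    achievable = data.frame(cbt_mm = c(20, 100), mGy = c(2, 4))),
    "exceeds")
})

test_that("classification regions are stable under grid refinement", {
  lim <- limit_curves(
    acceptable = data.frame(cbt_mm = c(20, 100), mGy = c(2, 4)),
    achievable = data.frame(cbt_mm = c(20, 100), mGy = c(1, 2)))
  rising <- drl_curve(make_fit("linear", c(a = 0.2, b = 0.02)), "CC",
                      c(20, 100))
  c1 <- classify_against_limits(rising, lim, grid_step = 1)
  c4 <- classify_against_limits(rising, lim, grid_step = 0.25)
  expect_equal(c1$regions$class, c4$regions$class)
  expect_true(all(abs(c1$regions$cbt_from - c4$regions$cbt_from) <= 1))
})

test_that("bundled synthetic limit fixtures load and classify a curve", {
  acc <- system.file("extdata", "limits_acceptable_synthetic.csv",
                     package = "mammodrl")
  ach <- system.file("extdata", "limits_achievable_synthetic.csv",
                     package = "mammodrl")
  lim <- read_limit_curves(acc, ach)
  expect_s3_class(lim, "limit_curves")
  cc <- drl_curve(exp2_params(0.94, 118.65, 7.30e-4, 15.85), "CC")
  cl <- classify_against_limits(cc, lim)
  expect_true(all(cl$grid$class %in%
                    c("below_achievable", "between", "above_acceptable")))
  # the reference curve sits under these synthetic acceptable limits at
  # large thickness
  expect_equal(cl$grid$class[cl$grid$cbt == 100], "below_achievable")
})
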