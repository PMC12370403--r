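ref_cc <- exp2_params(a = 0.94, tau1 = 118.65, c = 7.30e-4, tau2 = 15.85)
ref_mlo <- exp2_params(a = 0.912, tau1 = 89.31, c = 1.887e-14, tau2 = 3.1)

test_that("exact linear data are recovered to optimizer precision", {
  pts <- data.frame(cbt = seq(25, 95, 10), drl = 0.4 + 0.021 * seq(25, 95, 10))
  f <- fit_model(pts, "linear", seed = 1)
  expect_true(f$converged)
  expect_lt(abs(f$params[["a"]] - 0.4), 1e-9)
  expect_lt(abs(f$params[["b"]] - 0.021), 1e-10)
  expect_lt(f$gof$sse, 1e-18)
})

test_that("noiseless bi-exponential points give back their parameters", {
  truth <- c(0.94, 1 / 118.65, 7.30e-4, 1 / 15.85)
  t <- seq(25, 95, 10)
  pts <- data.frame(cbt = t,
                    drl = truth[1] * exp(truth[2] * t) +
                          truth[3] * exp(truth[4] * t))
  f <- fit_model(pts, "exp2", seed = 3)
  expect_true(f$converged)
  expect_lt(max(abs(f$params - truth) / truth), 1e-4)
  # canonical ordering: slow rate first
  expect_lte(f$params[["b"]], f$params[["d"]])
})

test_that("fitting is deterministic given the seed", {
  set.seed(99)
  t <- seq(25, 95, 10)
  pts <- data.frame(cbt = t,
                    drl = 0.9 * exp(t / 110) * exp(rnorm(8, 0, 0.03)))
  f1 <- fit_model(pts, "exp2", seed = 12)
  f2 <- fit_model(pts, "exp2", seed = 12)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$gof, f2$gof)
})

test_that("nested families never fit worse than their parent", {
  set.seed(7)
  t <- seq(25, 95, 10)
  for (i in 1:5) {
    y <- 0.8 * exp(t / 120) + rnorm(8, 0, 0.05)
    pts <- data.frame(cbt = t, drl = y)
    s_exp1 <- fit_model(pts, "exp1", seed = i)$gof$sse
    s_exp2 <- fit_model(pts, "exp2", seed = i)$gof$sse
    s_pow1 <- fit_model(pts, "power1", seed = i)$gof$sse
    s_pow2 <- fit_model(pts, "power2", seed = i)$gof$sse
    expect_lte(s_exp2, s_exp1 + 1e-10)
    expect_lte(s_pow2, s_pow1 + 1e-10)
  }
})

test_that("goodness-of-fit identities hold to machine precision", {
  set.seed(15)
  t <- seq(25, 95, 10)
  pts <- data.frame(cbt = t, drl = 0.9 * exp(t / 100) + rnorm(8, 0, 0.05))
  for (fam in c("linear", "power1", "power2", "exp1", "exp2")) {
    f <- fit_model(pts, fam, seed = 2)
    p <- mammodrl:::model_family(fam)$n_params
    n <- f$n_points
    expect_equal(f$gof$rmse, sqrt(f$gof$sse / (n - p)), tolerance = 1e-12)
    expect_equal(f$gof$adj_r2,
                 1 - (1 - f$gof$r2) * (n - 1) / (n - p), tolerance = 1e-12)
    sst <- sum((pts$drl - mean(pts$drl))^2)
    expect_equal(f$gof$r2, 1 - f$gof$sse / sst, tolerance = 1e-12)
  }
  # a perfect fit has sse 0, rmse 0, r2 1, adj_r2 1
  lin <- data.frame(cbt = 1:6, drl = 2 + 3 * (1:6))
  g <- gof_metrics(lin, c(2, 3), "linear")
  expect_equal(unlist(g), c(sse = 0, rmse = 0, r2 = 1, adj_r2 = 1))
})

test_that("published GOF tables are internally consistent with n = 8", {
  # RMSE = sqrt(SSE/(n-p)) and adjusted R2 from R2, for all five families
  sse_cc <- c(exp2 = 0.015, power2 = 0.020, exp1 = 0.024,
              linear = 0.054, power1 = 0.090)
  rmse_cc <- c(0.061, 0.063, 0.063, 0.095, 0.122)
  r2_cc <- c(0.988, 0.984, 0.981, 0.957, 0.928)
  adj_cc <- c(0.979, 0.978, 0.978, 0.950, 0.916)
  p <- c(4, 3, 2, 2, 2)
  expect_equal(sqrt(sse_cc / (8 - p)), rmse_cc, tolerance = 0.015,
               ignore_attr = TRUE)
  expect_equal(1 - (1 - r2_cc) * 7 / (8 - p), adj_cc, tolerance = 0.002,
               ignore_attr = TRUE)
})

test_that("model ranking is by SSE with honest tie-breaks", {
  t <- seq(25, 95, 10)
  mk <- function(fam, sse, adj, np, conv = TRUE) {
    structure(list(family = fam,
                   params = setNames(rep(1, np),
                                     head(c("a", "b", "c", "d"), np)),
                   gof = list(sse = sse, rmse = sqrt(sse / (8 - np)),
                              r2 = 1 - sse, adj_r2 = adj),
                   n_points = 8L, converged = conv,
                   n_restarts_used = 0L, seed = 1L),
              class = "drl_model_fit")
  }
  fits <- list(mk("linear", 0.054, 0.950, 2), mk("power1", 0.090, 0.916, 2),
               mk("power2", 0.020, 0.978, 3), mk("exp1", 0.024, 0.978, 2),
               mk("exp2", 0.015, 0.979, 4))
  ranked <- rank_models(fits)
  expect_equal(vapply(ranked, `[[`, "", "family"),
               c("exp2", "power2", "exp1", "linear", "power1"))
  # ties: equal SSE and adj R2 -> fewer parameters first
  tied <- list(mk("exp2", 0.02, 0.97, 4), mk("exp1", 0.02, 0.97, 2))
  expect_equal(rank_models(tied)[[1]]$family, "exp1")
  # a non-converged fit ranks last even with the lowest SSE
  nc <- list(mk("exp2", 0.001, 0.999, 4, conv = FALSE),
             mk("linear", 0.054, 0.950, 2))
  expect_equal(rank_models(nc)[[1]]$family, "linear")
})

test_that("curves built from published coefficients evaluate correctly", {
  cc <- drl_curve(ref_cc, "CC")
  mlo <- drl_curve(ref_mlo, "MLO")
  expect_equal(as.numeric(evaluate_curve(cc, c(50, 80, 100))),
               c(1.45, 1.96, 2.58), tolerance = 0.0051)
  expect_equal(as.numeric(evaluate_curve(mlo, c(50, 80, 100))),
               c(1.59, 2.24, 4.72), tolerance = 0.011)
  # extrapolation is flagged, not forbidden
  v <- evaluate_curve(cc, c(15, 50, 105))
  expect_equal(attr(v, "extrapolated"), c(TRUE, FALSE, TRUE))
  expect_error(evaluate_curve(cc, 0), "positive")
  # a bi-exponential with c = 0 is exactly the mono-exponential
  e2 <- drl_curve(exp2_params(0.9, 100, 0, 20), "CC")
  fit1 <- structure(list(family = "exp1", params = c(a = 0.9, b = 1 / 100),
                         gof = list(sse = NA, rmse = NA, r2 = NA,
                                    adj_r2 = NA),
                         n_points = NA_integer_, converged = NA,
                         n_restarts_used = 0L, seed = NA_integer_),
                    class = "drl_model_fit")
  e1 <- drl_curve(fit1, "CC")
  grid <- seq(20, 100, 5)
  expect_equal(as.numeric(evaluate_curve(e2, grid)),
               as.numeric(evaluate_curve(e1, grid)))
})

test_that("equation strings use the time-constant presentation", {
  s <- equation_string(drl_curve(ref_cc, "CC"))
  expect_match(s, "DRL_CC", fixed = TRUE)
  expect_match(s, "exp(CBT/119)", fixed = TRUE)  # 3 significant figures
  expect_match(s, "exp(CBT/15.8", fixed = TRUE)
})

test_that("fit_all selects among families and demands enough bins", {
  g <- generate_cohort(synth_config(n_centers = 5,
                                    exams_per_center = rep(200, 5),
                                    contamination = 0, seed = 41))
  b <- binned_drl_table(g$cohort, "CC")
  fa <- fit_all(b, seed = 41)
  expect_length(fa$fits, 5L)
  expect_s3_class(fa$curve, "drl_curve")
  expect_equal(fa$curve$fit$family, "exp2")
  expect_true(fa$curve$valid)
  # straight-line points: linear must rank no worse than power1
  pts_tab <- b
  pts_tab$drl <- 0.5 + 0.02 * pts_tab$representative_cbt
  fa_lin <- fit_all(pts_tab, seed = 1)
  fams <- vapply(fa_lin$fits, `[[`, "", "family")
  expect_lt(which(fams == "linear"), which(fams == "power1"))
  # fewer than 5 usable bins is an error recommending merging
  sparse <- b
  sparse$drl[1:4] <- NA
  expect_error(fit_all(sparse, seed = 1), "merging")
})

test_that("curve JSON carries both parameterizations at full precision", {
  j <- write_curve_json(drl_curve(ref_cc, "CC"))
  parsed <- jsonlite::fromJSON(j)
  expect_equal(parsed$fit$params_time_constant$tau1, 118.65)
  expect_equal(parsed$fit$params$b, 1 / 118.65, tolerance = 1e-12)
  expect_match(parsed$equation, "DRL_CC")
})
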