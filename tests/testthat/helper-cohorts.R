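# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# round to d decimals with halves away from zero (the convention used when
# printing percentages in reports), unlike base round()'s round-half-even
round_half_up <- function(x, d = 0) floor(x * 10^d + 0.5) / 10^d

# a drl_model_fit with exactly the given parameters (no fitting noise),
# for tests that need bitwise-exact curve values
make_fit <- function(family, params) {
  structure(list(family = family, params = params,
                 gof = list(sse = NA_real_, rmse = NA_real_,
                            r2 = NA_real_, adj_r2 = NA_real_),
                 n_points = NA_integer_, converged = TRUE,
                 n_restarts_used = 0L, seed = NA_integer_),
            class = "drl_model_fit")
}

# A minimal hand-enumerable cohort: n centers x per-center AGD vectors at a
# fixed view/CBT, one exam per record.
toy_cohort <- function(agd_by_center, view = "CC", cbt = 52,
                       mas = 70, kvp = 29, cf = 120) {
  rows <- do.call(rbind, lapply(names(agd_by_center), function(cid) {
    agd <- agd_by_center[[cid]]
    data.frame(center_id = cid,
               exam_id = sprintf("%s-%03d", cid, seq_along(agd)),
               view = view, laterality = "L", cbt = cbt,
               mas = mas, kvp = kvp, compression_force = cf,
               implant_present = FALSE, agd = agd,
               stringsAsFactors = FALSE)
  }))
  cohort_table(rows, provenance = "toy")
}

# One examination with explicit per-view fields, for filter-rule tests.
exam_rows <- function(exam_id, center = "C1", views = c("CC", "MLO"),
                      cf = 120, mas = 70, kvp = 29, cbt = 55,
                      implant = FALSE, agd = 1.4) {
  n <- length(views)
  data.frame(center_id = center, exam_id = exam_id, view = views,
             laterality = rep_len(c("L", "R"), n),
             cbt = rep_len(cbt, n), mas = rep_len(mas, n),
             kvp = rep_len(kvp, n),
             compression_force = rep_len(cf, n),
             implant_present = rep_len(implant, n),
             agd = rep_len(agd, n), stringsAsFactors = FALSE)
}

# Brute-force two-sided exact signed-rank p-value by enumerating all 2^n
# sign patterns (the independent oracle for signed_rank_test).
enumerate_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}
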