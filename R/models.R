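# Candidate DRL-vs-CBT model families and trust-region least-squares
# fitting.  The bi-exponential family is fitted in rate form
# a*exp(b*t) + c*exp(d*t) (better conditioned) with the canonical ordering
# b <= d to resolve the term-swap symmetry; the time-constant presentation
# a*exp(t/tau1) + c*exp(t/tau2) with tau = 1/rate is used for reporting.

MODEL_FAMILIES <- c("linear", "power1", "power2", "exp1", "exp2")

model_family <- function(name) {
  name <- match.arg(name, MODEL_FAMILIES)
  switch(name,
    linear = list(name = "linear", n_params = 2L,
                  par_names = c("a", "b"),
                  predict = function(p, t) p[1] + p[2] * t,
                  label = "a + b*t"),
    power1 = list(name = "power1", n_params = 2L,
                  par_names = c("a", "b"),
                  predict = function(p, t) p[1] * t^p[2],
                  label = "a*t^b"),
    power2 = list(name = "power2", n_params = 3L,
                  par_names = c("a", "b", "c"),
                  predict = function(p, t) p[1] * t^p[2] + p[3],
                  label = "a*t^b + c"),
    exp1 = list(name = "exp1", n_params = 2L,
                par_names = c("a", "b"),
                predict = function(p, t) p[1] * exp(p[2] * t),
                label = "a*exp(b*t)"),
    exp2 = list(name = "exp2", n_params = 4L,
                par_names = c("a", "b", "c", "d"),
                predict = function(p, t)
                  p[1] * exp(p[2] * t) + p[3] * exp(p[4] * t),
                label = "a*exp(b*t) + c*exp(d*t)")
  )
}

# Data-driven starting values (explicit policy: reproducible fits need one).
heuristic_starts <- function(fam, t, y) {
  eps <- max(1e-9, min(y[y > 0], na.rm = TRUE) * 1e-3)
  ylog <- log(pmax(y, eps))
  starts <- list()
  if (fam$name == "linear") {
    co <- stats::coef(stats::lm(y ~ t))
    starts <- list(unname(co))
  } else if (fam$name == "exp1") {
    co <- stats::coef(stats::lm(ylog ~ t))
    starts <- list(c(exp(co[1]), co[2]))
  } else if (fam$name == "power1") {
    co <- stats::coef(stats::lm(ylog ~ log(t)))
    starts <- list(c(exp(co[1]), co[2]))
  } else if (fam$name == "power2") {
    co <- stats::coef(stats::lm(ylog ~ log(t)))
    c0 <- min(y) / 2
    co2 <- stats::coef(stats::lm(log(pmax(y - c0, eps)) ~ log(t)))
    starts <- list(c(exp(co[1]), co[2], 0),
                   c(exp(co2[1]), co2[2], c0))
  } else if (fam$name == "exp2") {
    co <- stats::coef(stats::lm(ylog ~ t))
    a <- exp(co[1]); b <- co[2]
    starts <- list(c(a, b / 2, a * 1e-3, b * 2),
                   c(a, b, a * 1e-4, b * 3),
                   c(a / 2, b / 3, a / 2, b * 1.5))
    # classic peeling: slow component from the low-t half, fast component
    # from the log of the positive residuals at high t
    n <- length(t)
    lo <- order(t)[seq_len(ceiling(n / 2))]
    co_s <- stats::coef(stats::lm(ylog[lo] ~ t[lo]))
    a_s <- exp(co_s[1]); b_s <- co_s[2]
    r <- y - a_s * exp(b_s * t)
    pos <- which(r > 0 & t > stats::median(t))
    if (length(pos) >= 2) {
      co_f <- stats::coef(stats::lm(log(r[pos]) ~ t[pos]))
      starts <- c(starts, list(c(a_s, b_s, exp(co_f[1]), co_f[2])))
    }
  }
  lapply(starts, unname)
}

perturb_start <- function(p) {
  # multiplicative jitter on amplitudes, additive on rates/exponents
  p * exp(stats::rnorm(length(p), 0, 0.5)) *
    sample(c(1, 1, 1, -1), length(p), replace = TRUE)
}

model_sse <- function(fam, p, t, y) {
  r <- y - fam$predict(p, t)
  if (any(!is.finite(r))) return(Inf)
  sum(r^2)
}

#' Fit one DRL-vs-CBT model family by trust-region least squares
#'
#' Levenberg-Marquardt (trust-region-radius) nonlinear least squares with a
#' multistart policy: data-driven heuristic starting values plus
#' `n_restarts` randomized restarts under a fixed seed; the best
#' sum-of-squared-errors solution is kept, so results are deterministic
#' given the seed. For the nested families (`exp2` over `exp1`, `power2`
#' over `power1`) the nested optimum is used as an additional start, which
#' guarantees the nested-model SSE inequality up to optimizer tolerance.
#'
#' @param points data frame with columns `cbt` (mm) and `drl` (mGy).
#' @param family one of `"linear"`, `"power1"`, `"power2"`, `"exp1"`,
#'   `"exp2"`.
#' @param seed integer seed for the randomized restarts.
#' @param n_restarts number of randomized restarts per heuristic start.
#' @return A `drl_model_fit`: `family`, `params` (named, natural units),
#'   `gof` (`sse`, `rmse`, `r2`, `adj_r2`), `n_points`, `converged`,
#'   `n_restarts_used`, `seed`. Never throws on non-convergence: the best
#'   parameters found are returned with `converged = FALSE`.
#' @export
fit_model <- function(points, family, seed = 1L, n_restarts = 20L) {
  fam <- model_family(family)
  t <- as.numeric(points$cbt); y <- as.numeric(points$drl)
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(t)
  if (n <= fam$n_params) {
    stop(sprintf("need more than %d points to fit %s (got %d)",
                 fam$n_params, fam$name, n))
  }
  if (fam$name %in% c("power1", "power2") && any(t <= 0)) {
    stop("power-law families require cbt > 0")
  }

  starts <- heuristic_starts(fam, t, y)
  # nested-optimum start for the richer families
  if (fam$name == "exp2") {
    sub <- fit_model(points[ok, , drop = FALSE], "exp1", seed = seed,
                     n_restarts = n_restarts)
    starts <- c(starts, list(c(sub$params[["a"]], sub$params[["b"]],
                               0, sub$params[["b"]] * 2)))
  } else if (fam$name == "power2") {
    sub <- fit_model(points[ok, , drop = FALSE], "power1", seed = seed,
                     n_restarts = n_restarts)
    starts <- c(starts, list(c(sub$params[["a"]], sub$params[["b"]], 0)))
  }

  resid_fn <- function(p) {
    r <- y - fam$predict(p, t)
    r[!is.finite(r)] <- 1e6
    r
  }
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                    gtol = 1e-10, maxiter = 1000,
                                    maxfev = 10000)
  best <- NULL
  try_start <- function(p0) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, control = ctl)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    # info 1-3: ftol/ptol criteria met; 4: gradient criterion met
    list(par = unname(fit$par), sse = sum(fit$fvec^2),
         converged = fit$info %in% 1:4)
  }
  all_starts <- starts
  with_private_seed(seed, {
    for (s in starts) {
      for (i in seq_len(n_restarts)) {
        all_starts[[length(all_starts) + 1L]] <- perturb_start(s)
      }
    }
  })
  for (p0 in all_starts) {
    cand <- try_start(p0)
    if (is.null(cand) || !is.finite(cand$sse)) next
    if (is.null(best) || cand$sse < best$sse ||
        (cand$sse == best$sse && cand$converged && !best$converged)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    best <- list(par = starts[[1]], sse = model_sse(fam, starts[[1]], t, y),
                 converged = FALSE)
  }
  # polish: an iteration-capped best candidate usually converges when
  # restarted from its own endpoint
  for (k in 1:2) {
    if (best$converged) break
    again <- try_start(best$par)
    if (is.null(again) || !is.finite(again$sse) || again$sse > best$sse) {
      break
    }
    best <- again
  }
  par <- best$par
  if (fam$name == "exp2" && par[2] > par[4]) {
    par <- par[c(3, 4, 1, 2)]  # canonical rate ordering b <= d
  }
  par <- setNames(par, fam$par_names)
  structure(list(
    family = fam$name,
    params = par,
    gof = gof_metrics(data.frame(cbt = t, drl = y), par, fam$name),
    n_points = n,
    converged = isTRUE(best$converged),
    n_restarts_used = length(all_starts) - length(starts),
    seed = as.integer(seed)),
    class = "drl_model_fit")
}

#' Goodness-of-fit metrics for a fitted model
#'
#' Conventions: `sse` is the residual sum of squares; `rmse =
#' sqrt(sse / (n - p))` (residual degrees of freedom, as nonlinear
#' regression toolboxes report it); `r2 = 1 - sse/sst` with `sst` the total
#' sum of squares of the fitted y-values about their mean; `adj_r2 =
#' 1 - (1 - r2) (n - 1)/(n - p)`.
#'
#' @param points data frame with `cbt`, `drl`.
#' @param params named or positional parameter vector.
#' @param family family name.
#' @return List `sse`, `rmse`, `r2`, `adj_r2`.
#' @export
gof_metrics <- function(points, params, family) {
  fam <- model_family(family)
  t <- as.numeric(points$cbt); y <- as.numeric(points$drl)
  n <- length(t); p <- fam$n_params
  res <- y - fam$predict(unname(params), t)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  list(sse = sse,
       rmse = sqrt(sse / (n - p)),
       r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p))
}

#' Rank fitted models by goodness of fit
#'
#' Ascending SSE; ties broken by higher adjusted R-squared, then fewer
#' parameters. Non-converged fits rank last regardless of SSE.
#'
#' @param fits list of `drl_model_fit` objects fitted to the same points.
#' @return The list reordered, best first.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) > 0,
            all(vapply(fits, inherits, logical(1), "drl_model_fit")))
  npts <- unique(vapply(fits, `[[`, numeric(1), "n_points"))
  if (length(npts) != 1L) stop("fits were not made on identical points")
  key_nc <- !vapply(fits, `[[`, logical(1), "converged")
  key_sse <- vapply(fits, function(f) f$gof$sse, numeric(1))
  key_adj <- vapply(fits, function(f) f$gof$adj_r2, numeric(1))
  key_np <- vapply(fits, function(f)
    model_family(f$family)$n_params, integer(1))
  fits[order(key_nc, key_sse, -key_adj, key_np)]
}

#' @export
print.drl_model_fit <- function(x, ...) {
  cat(sprintf("<drl_model_fit> %s: %s\n", x$family,
              model_family(x$family)$label))
  cat("  params:", paste(sprintf("%s = %.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  SSE %.4g  RMSE %.4g  R2 %.4f  adjR2 %.4f  (n = %d%s)\n",
              x$gof$sse, x$gof$rmse, x$gof$r2, x$gof$adj_r2, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Construct a continuous DRL curve from a model fit
#'
#' @param fit a `drl_model_fit` (or, for curves built from published
#'   coefficients, the output of [exp2_params()]).
#' @param view `"CC"` or `"MLO"`.
#' @param domain fitted thickness span `[lo, hi]`, mm; evaluation outside is
#'   permitted but flagged as extrapolation.
#' @return A `drl_curve`.
#' @export
drl_curve <- function(fit, view, domain = c(20, 100)) {
  stopifnot(inherits(fit, "drl_model_fit"), length(domain) == 2L,
            domain[1] < domain[2])
  crv <- structure(list(view = toupper(view), fit = fit,
                        domain = as.numeric(domain)),
                   class = "drl_curve")
  vals <- evaluate_curve(crv, seq(domain[1], domain[2], length.out = 81))
  crv$valid <- all(vals > 0)
  crv
}

#' Bi-exponential parameters in time-constant form
#'
#' Builds a `drl_model_fit` for the bi-exponential family from published
#' amplitude/time-constant coefficients `a*exp(t/tau1) + c*exp(t/tau2)`,
#' for example a national reference equation. Goodness-of-fit entries are
#' `NA` (no fitting occurred).
#'
#' @param a,tau1,c,tau2 amplitudes (mGy) and time constants (mm).
#' @return A `drl_model_fit` with rates `b = 1/tau1`, `d = 1/tau2`.
#' @export
exp2_params <- function(a, tau1, c, tau2) {
  par <- c(a = a, b = 1 / tau1, c = c, d = 1 / tau2)
  if (par[["b"]] > par[["d"]]) par <- par[c("c", "d", "a", "b")]
  names(par) <- c("a", "b", "c", "d")
  structure(list(family = "exp2", params = par,
                 gof = list(sse = NA_real_, rmse = NA_real_,
                            r2 = NA_real_, adj_r2 = NA_real_),
                 n_points = NA_integer_, converged = NA,
                 n_restarts_used = 0L, seed = NA_integer_),
            class = "drl_model_fit")
}

#' Evaluate a DRL curve at given thicknesses
#'
#' @param curve a [drl_curve()].
#' @param cbt numeric vector, mm (must be positive).
#' @return Numeric vector of DRLs, mGy, with attribute `extrapolated`
#'   marking points outside the fitted domain.
#' @export
evaluate_curve <- function(curve, cbt) {
  stopifnot(inherits(curve, "drl_curve") || inherits(curve, "list"))
  cbt <- as.numeric(cbt)
  if (any(cbt <= 0)) stop("cbt must be positive")
  fam <- model_family(curve$fit$family)
  v <- fam$predict(unname(curve$fit$params), cbt)
  attr(v, "extrapolated") <- cbt < curve$domain[1] | cbt > curve$domain[2]
  v
}

#' Render a curve as an equation string
#'
#' Bi-exponential curves are shown in time-constant form
#' `DRL(t) = a*exp(t/tau1) + c*exp(t/tau2)`; other families in their
#' natural form. Coefficients use `digits` significant figures (full
#' precision is always kept in the object and its JSON serialization).
#'
#' @param curve a [drl_curve()].
#' @param digits significant figures for display.
#' @return Character scalar.
#' @export
equation_string <- function(curve, digits = 3) {
  p <- curve$fit$params
  g <- function(v) signif(v, digits)
  body <- switch(curve$fit$family,
    linear = sprintf("%g + %g*CBT", g(p[["a"]]), g(p[["b"]])),
    power1 = sprintf("%g*CBT^%g", g(p[["a"]]), g(p[["b"]])),
    power2 = sprintf("%g*CBT^%g + %g", g(p[["a"]]), g(p[["b"]]),
                     g(p[["c"]])),
    exp1 = sprintf("%g*exp(CBT/%g)", g(p[["a"]]), g(1 / p[["b"]])),
    exp2 = sprintf("%g*exp(CBT/%g) + %g*exp(CBT/%g)",
                   g(p[["a"]]), g(1 / p[["b"]]),
                   g(p[["c"]]), g(1 / p[["d"]])))
  sprintf("DRL_%s(CBT) [mGy] = %s", curve$view, body)
}

#' @export
print.drl_curve <- function(x, ...) {
  cat("<drl_curve>", equation_string(x), "\n")
  cat(sprintf("  domain [%g, %g] mm; family %s%s\n", x$domain[1],
              x$domain[2], x$fit$family,
              if (isTRUE(x$valid)) "" else "; WARNING: non-positive values"))
  invisible(x)
}

#' Fit all candidate families to a binned DRL table and select the best
#'
#' Fits every requested family to the (representative CBT, DRL) points of
#' the non-empty bins, ranks by SSE (see [rank_models()]), and returns the
#' winner as a continuous [drl_curve()].
#'
#' @param table a [binned_drl_table()].
#' @param families character vector of family names.
#' @param seed integer seed passed to every [fit_model()].
#' @return List `fits` (ranked), `curve` (best family as `drl_curve`),
#'   `points` (the fitted points).
#' @export
fit_all <- function(table, families = MODEL_FAMILIES, seed = 1L) {
  stopifnot(inherits(table, "binned_drl_table"))
  pts <- data.frame(cbt = table$representative_cbt, drl = table$drl)
  pts <- pts[!is.na(pts$drl), , drop = FALSE]
  if (nrow(pts) < 5L) {
    stop("only ", nrow(pts), " non-empty bins; at least 5 are needed - ",
         "consider merging adjacent edge bins (bin_scheme(merge_edges=))")
  }
  fits <- lapply(families, function(f) fit_model(pts, f, seed = seed))
  ranked <- rank_models(fits)
  dom <- range(c(table$bin_lo[!table$empty], table$bin_hi[!table$empty]))
  list(fits = ranked,
       curve = drl_curve(ranked[[1]], attr(table, "view"), domain = dom),
       points = pts)
}

#' Serialize a DRL curve (or list of fits) as JSON
#'
#' @param curve a [drl_curve()].
#' @param fits optional list of ranked `drl_model_fit`s to embed.
#' @param path output path; `NULL` returns the JSON string.
#' @export
write_curve_json <- function(curve, fits = NULL, path = NULL) {
  fit_payload <- function(f) {
    out <- list(family = f$family, params = as.list(f$params),
                gof = f$gof, n_points = f$n_points,
                converged = f$converged,
                n_restarts_used = f$n_restarts_used, seed = f$seed)
    if (f$family == "exp2") {
      out$params_time_constant <- list(
        a = f$params[["a"]], tau1 = 1 / f$params[["b"]],
        c = f$params[["c"]], tau2 = 1 / f$params[["d"]])
    }
    out
  }
  payload <- list(view = curve$view, domain = curve$domain,
                  equation = equation_string(curve),
                  valid = curve$valid %||% NA,
                  fit = fit_payload(curve$fit))
  if (!is.null(fits)) payload$all_fits <- lapply(fits, fit_payload)
  j <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                        digits = NA, na = "null")
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}
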