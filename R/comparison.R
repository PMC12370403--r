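#' Absolute percent difference relative to a reference value
#'
#' `|a - ref| / ref * 100`. Used with the equation-approach DRL as the
#' reference when comparing the range approach to the fitted curve.
#'
#' @param a value to compare, mGy.
#' @param ref reference value, mGy (must be positive).
#' @return Percent difference.
#' @export
percent_diff <- function(a, ref) {
  if (any(ref <= 0)) stop("reference value must be positive")
  abs(a - ref) / ref * 100
}

#' Percent difference relative to the simplest-approach DRL
#'
#' Discussion-level comparison convention: the single typical-thickness DRL
#' is the denominator (a different convention from [percent_diff()], which
#' divides by the equation value; both appear in DRL reporting and each is
#' bound to its context).
#'
#' @param value DRL being compared, mGy.
#' @param simplest the typical-thickness DRL, mGy (positive).
#' @return Percent difference.
#' @export
compare_to_simplest <- function(value, simplest) {
  if (any(simplest <= 0)) stop("simplest DRL must be positive")
  abs(value - simplest) / simplest * 100
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test. Zero differences are dropped
#' (Wilcoxon convention) and ties are mid-ranked. For `n <= 25` pairs the
#' exact null distribution of the positive-rank sum is computed by
#' convolution over the (possibly tied) rank values, so p-values remain
#' exact under ties; above that, a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param diffs numeric vector of signed differences.
#' @param exact_max largest n for which the exact distribution is used.
#' @return List `statistic` (the smaller of the positive/negative rank
#'   sums), `w_plus`, `p_value`, `n_pairs` (nonzero pairs), `method`,
#'   `degenerate` (`TRUE` when all differences are zero; then `p_value`
#'   is 1).
#' @export
signed_rank_test <- function(diffs, exact_max = 25L) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, w_plus = NA_real_, p_value = 1,
                n_pairs = 0L, method = "degenerate (all zero differences)",
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_max) {
    # distribution of 2*W+ over all 2^n sign assignments, by convolution
    r2 <- round(2 * r)
    total <- sum(r2)
    dist <- numeric(total + 1L)  # index k+1 = count of patterns with 2W+ = k
    dist[1L] <- 1
    for (rv in r2) {
      shifted <- c(numeric(rv), dist[seq_len(total + 1L - rv)])
      dist <- dist + shifted
    }
    w2 <- round(2 * w_plus)
    p_le <- sum(dist[seq_len(w2 + 1L)]) / 2^n
    p_ge <- sum(dist[seq.int(w2 + 1L, total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (rank-sum convolution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = min(w_plus, w_minus), w_plus = w_plus,
       p_value = p, n_pairs = n, method = method, degenerate = FALSE)
}

#' Compare the continuous (equation) and range-based DRL approaches
#'
#' Evaluates the fitted curve and the per-bin step function on a thickness
#' grid, computes pointwise percent differences (denominator: the equation
#' value), and tests the signed differences (range minus equation) with a
#' two-sided Wilcoxon signed-rank test.
#'
#' @param curve a [drl_curve()].
#' @param table a [binned_drl_table()] for the same view.
#' @param grid_step grid spacing, mm (default 1 mm over the shared domain).
#' @param simplest optional typical-thickness DRL, mGy, to include
#'   simplest-approach percent differences.
#' @return A `drl_comparison`: data frame `grid` with columns `cbt`,
#'   `eq_drl`, `range_drl`, `pct_diff_range`, (optionally
#'   `pct_diff_simplest`), plus fields `view`, `wilcoxon`, `simplest_drl`.
#' @export
compare_equation_vs_ranges <- function(curve, table, grid_step = 1,
                                       simplest = NULL) {
  stopifnot(inherits(curve, "drl_curve"), inherits(table, "binned_drl_table"))
  if (!identical(curve$view, attr(table, "view"))) {
    stop("curve and table views differ")
  }
  breaks <- attr(table, "scheme")$breaks
  lo <- max(curve$domain[1], breaks[1])
  hi <- min(curve$domain[2], breaks[length(breaks)])
  if (lo >= hi) stop("curve and table domains are disjoint")
  grid <- seq(lo, hi, by = grid_step)
  eq <- as.numeric(evaluate_curve(curve, grid))
  rng <- range_drl_at(table, grid)
  ok <- !is.na(rng)
  df <- data.frame(cbt = grid, eq_drl = eq, range_drl = rng,
                   pct_diff_range = ifelse(ok, percent_diff(rng, eq), NA))
  if (!is.null(simplest)) {
    df$pct_diff_simplest <- compare_to_simplest(eq, simplest)
  }
  wt <- signed_rank_test(rng[ok] - eq[ok])
  structure(list(view = curve$view, grid = df, wilcoxon = wt,
                 simplest_drl = simplest %||% NA_real_),
            class = "drl_comparison")
}

#' @export
print.drl_comparison <- function(x, ...) {
  cat(sprintf("<drl_comparison> view %s, %d grid points\n",
              x$view, nrow(x$grid)))
  pd <- x$grid$pct_diff_range
  cat(sprintf("  |range - equation|/equation: median %.1f%%, max %.1f%%\n",
              stats::median(pd, na.rm = TRUE), max(pd, na.rm = TRUE)))
  w <- x$wilcoxon
  cat(sprintf("  Wilcoxon signed-rank: W = %g, p = %.3g (%s, n = %d)\n",
              w$statistic, w$p_value, w$method, w$n_pairs))
  invisible(x)
}

#' Read acceptable/achievable limit curves from CSV
#'
#' Each file holds two columns `cbt_mm`, `mGy`; limits between tabulated
#' thicknesses are interpolated piecewise-linearly. The achievable limit
#' must not exceed the acceptable limit anywhere they are both defined.
#'
#' @param acceptable,achievable paths to two-column CSV files.
#' @return A `limit_curves` list with `acceptable` and `achievable` tables.
#' @export
read_limit_curves <- function(acceptable, achievable) {
  rd <- function(p) {
    d <- utils::read.csv(p)
    if (!all(c("cbt_mm", "mGy") %in% names(d))) {
      stop("limit file must have columns cbt_mm, mGy: ", p)
    }
    d[order(d$cbt_mm), c("cbt_mm", "mGy")]
  }
  limit_curves(rd(acceptable), rd(achievable))
}

#' Construct limit curves from tables
#' @param acceptable,achievable data frames with `cbt_mm`, `mGy`.
#' @return A `limit_curves` object.
#' @export
limit_curves <- function(acceptable, achievable) {
  shared <- intersect(acceptable$cbt_mm, achievable$cbt_mm)
  if (length(shared)) {
    a <- acceptable$mGy[match(shared, acceptable$cbt_mm)]
    b <- achievable$mGy[match(shared, achievable$cbt_mm)]
    if (any(b > a)) stop("achievable limit exceeds acceptable limit")
  }
  structure(list(acceptable = acceptable, achievable = achievable,
                 interpolation = "piecewise-linear"),
            class = "limit_curves")
}

#' Classify a DRL curve against guideline limit curves
#'
#' Pointwise classification of the fitted DRL against interpolated
#' acceptable/achievable guideline limits. Boundaries are inclusive
#' downward: a DRL equal to a limit is assigned the category below it.
#' Grid points outside a limit table's span are flagged `uncovered`.
#'
#' @param curve a [drl_curve()].
#' @param limits a [limit_curves()].
#' @param grid_step grid spacing, mm.
#' @return A `limit_classification`: data frame `grid` (`cbt`, `drl`,
#'   `acceptable`, `achievable`, `class`) and `regions`, a run-length
#'   summary of contiguous classification regions.
#' @export
classify_against_limits <- function(curve, limits, grid_step = 1) {
  stopifnot(inherits(curve, "drl_curve"), inherits(limits, "limit_curves"))
  grid <- seq(curve$domain[1], curve$domain[2], by = grid_step)
  v <- as.numeric(evaluate_curve(curve, grid))
  interp <- function(tab) {
    out <- rep(NA_real_, length(grid))
    inside <- grid >= min(tab$cbt_mm) & grid <= max(tab$cbt_mm)
    if (any(inside)) {
      out[inside] <- approx(tab$cbt_mm, tab$mGy, grid[inside])$y
    }
    out
  }
  acc <- interp(limits$acceptable)
  ach <- interp(limits$achievable)
  cls <- ifelse(is.na(acc) | is.na(ach), "uncovered",
         ifelse(v > acc, "above_acceptable",
         ifelse(v <= ach, "below_achievable", "between")))
  rle_cls <- rle(cls)
  ends <- cumsum(rle_cls$lengths)
  starts <- ends - rle_cls$lengths + 1L
  regions <- data.frame(class = rle_cls$values,
                        cbt_from = grid[starts], cbt_to = grid[ends])
  structure(list(grid = data.frame(cbt = grid, drl = v, acceptable = acc,
                                   achievable = ach, class = cls),
                 regions = regions),
            class = "limit_classification")
}

#' Serialize a comparison report
#' @param comparison a `drl_comparison`.
#' @param path output path ending in `.csv` (grid only) or `.json`.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "drl_comparison"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(comparison$grid, path, row.names = FALSE)
  } else if (ext == "json") {
    writeLines(jsonlite::toJSON(unclass(comparison), auto_unbox = TRUE,
                                pretty = TRUE, digits = NA, na = "null"),
               path)
  } else stop("unsupported extension: ", ext)
  invisible(path)
}
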