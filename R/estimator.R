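#' Thickness binning scheme for range-based DRLs
#'
#' Bins are half-open `[b, b + width)` except the last, which is closed
#' `[hi - width, hi]` so that the survey's upper thickness limit is kept.
#' The default covers 20-100 mm in 10-mm increments (8 bins with nominal
#' centers 25, 35, ..., 95 mm).
#'
#' @param lo,hi domain bounds, mm. `(hi - lo)` must be divisible by `width`.
#' @param width bin width, mm.
#' @param representative `"midpoint"` (nominal integer bin center, default)
#'   or `"bin_mean"` (mean observed CBT of the bin's records).
#' @param merge_edges optional integer vector of length 2: numbers of
#'   leading/trailing bins to merge into single wider edge bins, the
#'   mitigation for sparse extreme thicknesses.
#' @return A `bin_scheme` with a `breaks` element.
#' @export
bin_scheme <- function(lo = 20, hi = 100, width = 10,
                       representative = c("midpoint", "bin_mean"),
                       merge_edges = c(0L, 0L)) {
  stopifnot(hi > lo, width > 0)
  if ((hi - lo) %% width != 0) {
    stop("(hi - lo) must be divisible by width")
  }
  representative <- match.arg(representative)
  breaks <- seq(lo, hi, by = width)
  # merge_edges = c(m1, m2): the first m1 bins become one wide bin, the
  # last m2 bins become one wide bin (m <= 1 leaves that edge unchanged)
  merge_edges <- as.integer(rep_len(merge_edges, 2L))
  k <- length(breaks)
  stopifnot(sum(pmax(merge_edges, 1L)) <= k - 1L)
  drop_idx <- c(if (merge_edges[1] > 1) seq(2L, merge_edges[1]),
                if (merge_edges[2] > 1) seq(k - merge_edges[2] + 1L, k - 1L))
  if (length(drop_idx)) breaks <- breaks[-drop_idx]
  structure(list(lo = lo, hi = hi, width = width,
                 representative = representative, breaks = breaks),
            class = "bin_scheme")
}

bin_index <- function(cbt, breaks) {
  # half-open [b_i, b_{i+1}) except the last bin, closed at the top
  idx <- findInterval(cbt, breaks, rightmost.closed = TRUE)
  idx[cbt < breaks[1] | cbt > breaks[length(breaks)]] <- NA_integer_
  idx
}

#' Per-center median AGD within a thickness range
#'
#' @param table filtered [cohort_table()].
#' @param view `"CC"` or `"MLO"` (left and right lateralities pooled).
#' @param cbt_range numeric length-2, half-open `[lo, hi)` in mm; pass
#'   `closed_hi = TRUE` for a closed upper bound (last bin).
#' @param closed_hi include records at exactly `hi`.
#' @return Named numeric vector of median AGD (mGy) per center; centers with
#'   no in-range records are omitted, never zero-filled.
#' @export
center_medians <- function(table, view, cbt_range, closed_hi = FALSE) {
  stopifnot(inherits(table, "cohort_table"), length(cbt_range) == 2L)
  sel <- table$view == toupper(view) & table$cbt >= cbt_range[1] &
    (if (closed_hi) table$cbt <= cbt_range[2] else table$cbt < cbt_range[2])
  sel <- sel & !is.na(table$agd)
  if (!any(sel)) return(setNames(numeric(0), character(0)))
  vapply(split(table$agd[sel], table$center_id[sel]), stats::median,
         numeric(1))
}

#' 75th percentile of center medians (the DRL statistic)
#'
#' @param medians numeric vector of per-center median doses, mGy.
#' @param prob percentile as a fraction (0.75 for a DRL).
#' @param type quantile convention: `"linear"` (interpolation between
#'   closest ranks, the common scientific-software default) or
#'   `"nearest_rank"`. With few centers the convention matters; it is
#'   recorded in all serialized outputs.
#' @return The DRL, mGy.
#' @export
drl_percentile <- function(medians, prob = 0.75,
                           type = c("linear", "nearest_rank")) {
  type <- match.arg(type)
  medians <- medians[!is.na(medians)]
  if (length(medians) == 0L) stop("no center medians supplied")
  unname(quantile(medians, prob,
                  type = if (type == "linear") 7L else 1L))
}

#' DRL for the single typical-thickness window (simplest approach)
#'
#' The conventional reference statistic: the 75th percentile of per-center
#' median AGD over breasts in a single window, by default 50 +/- 5 mm.
#'
#' @param table filtered [cohort_table()].
#' @param view `"CC"` or `"MLO"`.
#' @param center_cbt window center, mm.
#' @param half_width half-width, mm; the window is
#'   `[center - half_width, center + half_width)`.
#' @param type percentile convention, see [drl_percentile()].
#' @return The DRL, mGy.
#' @export
simplest_drl <- function(table, view, center_cbt = 50, half_width = 5,
                         type = c("linear", "nearest_rank")) {
  rng <- c(center_cbt - half_width, center_cbt + half_width)
  med <- center_medians(table, view, rng)
  if (length(med) == 0L) {
    stop(sprintf("no records in CBT range [%g, %g) mm for view %s",
                 rng[1], rng[2], view))
  }
  drl_percentile(med, type = match.arg(type))
}

#' Distribution-free confidence interval for a median
#'
#' Order-statistic (binomial-rank) interval: with `n` sorted values the
#' interval is `(x_(l), x_(n - l + 1))` where
#' `l = qbinom(alpha/2, n, 1/2)`, giving coverage at least `level`. Exact,
#' deterministic and free of distributional assumptions. For `n < 6` no
#' nondegenerate interval at 95% exists, so the full data range is returned
#' with `small_n = TRUE`.
#'
#' @param values numeric vector, mGy.
#' @param level confidence level, default 0.95.
#' @return List `lo`, `hi`, `level`, `n`, `small_n`, and the ranks used.
#' @export
median_ci <- function(values, level = 0.95) {
  values <- sort(values[!is.na(values)])
  n <- length(values)
  if (n == 0L) stop("no values supplied")
  if (n < 6L) {
    return(list(lo = values[1], hi = values[n], level = level, n = n,
                small_n = TRUE, ranks = c(1L, n)))
  }
  alpha <- 1 - level
  l <- qbinom(alpha / 2, n, 0.5)
  l <- max(1L, as.integer(l))
  u <- n - l + 1L
  list(lo = values[l], hi = values[u], level = level, n = n,
       small_n = FALSE, ranks = c(l, u))
}

#' Per-bin DRL table (improved, range-based approach)
#'
#' For each thickness bin: per-center median AGD, the 75th-percentile DRL,
#' record count, pooled median AGD with its 95% order-statistic confidence
#' interval, and a representative thickness for curve fitting. Bins with no
#' contributing centers are kept as empty rows (flagged), not dropped.
#'
#' @param table filtered [cohort_table()].
#' @param view `"CC"` or `"MLO"`.
#' @param scheme a [bin_scheme()].
#' @param type percentile convention, see [drl_percentile()].
#' @param low_n_threshold centers contributing fewer in-bin records are
#'   listed in the row's `low_n_centers` flag.
#' @return A `binned_drl_table`: data frame with columns `bin_lo`, `bin_hi`,
#'   `representative_cbt`, `n_records`, `n_centers`, `drl`, `median_agd`,
#'   `ci_lo`, `ci_hi`, `ci_small_n`, `empty`; attributes `view`, `scheme`,
#'   `percentile_type`, `center_medians` (list of named vectors) and
#'   `low_n_centers`.
#' @export
binned_drl_table <- function(table, view, scheme = bin_scheme(),
                             type = c("linear", "nearest_rank"),
                             low_n_threshold = 20L) {
  stopifnot(inherits(table, "cohort_table"), inherits(scheme, "bin_scheme"))
  type <- match.arg(type)
  view <- toupper(view)
  if (nrow(table) == 0L) warning("empty cohort table")
  breaks <- scheme$breaks
  nb <- length(breaks) - 1L
  sel <- table$view == view & !is.na(table$cbt) & !is.na(table$agd)
  idx <- bin_index(table$cbt[sel], breaks)
  agd <- table$agd[sel]; ctr <- table$center_id[sel]; cbt <- table$cbt[sel]

  rows <- vector("list", nb)
  med_list <- vector("list", nb)
  low_n <- vector("list", nb)
  for (b in seq_len(nb)) {
    in_b <- !is.na(idx) & idx == b
    n_rec <- sum(in_b)
    meds <- if (n_rec) vapply(split(agd[in_b], ctr[in_b]), stats::median,
                              numeric(1)) else setNames(numeric(0), NULL)
    counts <- if (n_rec) table(ctr[in_b]) else integer(0)
    low_n[[b]] <- names(counts)[counts < low_n_threshold]
    med_list[[b]] <- meds
    rep_cbt <- if (scheme$representative == "midpoint" || n_rec == 0L) {
      (breaks[b] + breaks[b + 1L]) / 2
    } else mean(cbt[in_b])
    if (n_rec) {
      ci <- median_ci(agd[in_b])
      rows[[b]] <- data.frame(
        bin_lo = breaks[b], bin_hi = breaks[b + 1L],
        representative_cbt = rep_cbt, n_records = n_rec,
        n_centers = length(meds),
        drl = drl_percentile(meds, type = type),
        median_agd = stats::median(agd[in_b]),
        ci_lo = ci$lo, ci_hi = ci$hi, ci_small_n = ci$small_n,
        empty = FALSE)
    } else {
      rows[[b]] <- data.frame(
        bin_lo = breaks[b], bin_hi = breaks[b + 1L],
        representative_cbt = rep_cbt, n_records = 0L, n_centers = 0L,
        drl = NA_real_, median_agd = NA_real_, ci_lo = NA_real_,
        ci_hi = NA_real_, ci_small_n = NA, empty = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, view = view, scheme = scheme, percentile_type = type,
            center_medians = med_list, low_n_centers = low_n,
            class = c("binned_drl_table", "data.frame"))
}

#' @export
print.binned_drl_table <- function(x, ...) {
  cat(sprintf("<binned_drl_table> view %s, %d bins (percentile: %s)\n",
              attr(x, "view"), nrow(x), attr(x, "percentile_type")))
  print(as.data.frame(x))
  invisible(x)
}

#' Look up the range-approach DRL for a thickness
#'
#' Step-function evaluation: each thickness is assigned the DRL of the
#' 10-mm bin containing it (half-open bins, last bin closed at the top).
#'
#' @param table a [binned_drl_table()].
#' @param cbt numeric vector of thicknesses, mm.
#' @return DRL values, mGy; `NA` outside the binned domain or in empty bins.
#' @export
range_drl_at <- function(table, cbt) {
  stopifnot(inherits(table, "binned_drl_table"))
  breaks <- attr(table, "scheme")$breaks
  idx <- bin_index(cbt, breaks)
  out <- rep(NA_real_, length(cbt))
  ok <- !is.na(idx)
  out[ok] <- table$drl[idx[ok]]
  out
}

#' Serialize a binned DRL table
#' @param table a [binned_drl_table()].
#' @param path output path ending in `.csv` or `.json`.
#' @export
write_binned_drl <- function(table, path) {
  stopifnot(inherits(table, "binned_drl_table"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  } else if (ext == "json") {
    payload <- list(
      view = attr(table, "view"),
      percentile_type = attr(table, "percentile_type"),
      breaks = attr(table, "scheme")$breaks,
      rows = as.data.frame(table),
      center_medians = lapply(attr(table, "center_medians"), as.list),
      low_n_centers = attr(table, "low_n_centers"))
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, na = "null"), path)
  } else stop("unsupported extension: ", ext)
  invisible(path)
}
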