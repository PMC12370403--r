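#' Exclusion-rule configuration for a DRL survey
#'
#' Defaults encode the conventional quality screens for mammographic dose
#' surveys: only standard CC/MLO projections are kept; an examination is
#' removed in toto when any of its views has an extreme compression force
#' (0 N, or above `cf_max`), a tube loading below `mas_min` (erroneous
#' exposure), a tube voltage of 0 kVp, a compressed breast thickness above
#' `cbt_max` (too sparse for reliable statistics), or a breast implant.
#'
#' @param cf_max maximum plausible compression force, N. Values strictly
#'   above are excluded; `cf_max` itself is kept.
#' @param cf_exclude_zero exclude records with 0 N compression force.
#' @param mas_min records with `0 <= mAs < mas_min` are excluded
#'   (half-open: `mas_min` itself is kept).
#' @param kvp_exclude_zero exclude records with 0 kVp.
#' @param cbt_max maximum thickness, mm; strictly above is excluded
#'   (`cbt_max` itself kept).
#' @param allowed_views views retained (records with other views dropped
#'   record-wise before the examination-level rules).
#' @param exclude_implants exclude examinations flagged implant-present.
#' @param exam_level if `TRUE` (default) rules 2-6 remove the whole
#'   examination when any view violates; if `FALSE` only offending records.
#' @return A `filter_config` list.
#' @export
filter_config <- function(cf_max = 200, cf_exclude_zero = TRUE,
                          mas_min = 10, kvp_exclude_zero = TRUE,
                          cbt_max = 100, allowed_views = c("CC", "MLO"),
                          exclude_implants = TRUE, exam_level = TRUE) {
  stopifnot(cf_max > 0, mas_min >= 0, cbt_max > 0)
  structure(list(cf_max = cf_max, cf_exclude_zero = cf_exclude_zero,
                 mas_min = mas_min, kvp_exclude_zero = kvp_exclude_zero,
                 cbt_max = cbt_max, allowed_views = toupper(allowed_views),
                 exclude_implants = exclude_implants,
                 exam_level = exam_level),
            class = "filter_config")
}

#' Partition a cohort into examination groups
#'
#' @param table a [cohort_table()].
#' @return Named list of row-index vectors, one per `(center_id, exam_id)`,
#'   in first-appearance order.
#' @export
group_exams <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) == 0L) return(list())
  key <- paste(table$center_id, table$exam_id, sep = "\r")
  split(seq_len(nrow(table)), factor(key, levels = unique(key)))
}

FILTER_RULES <- c("non_standard_view", "compression_force", "low_mas",
                  "zero_kvp", "cbt_above_max", "implant_present")

#' Apply survey exclusion rules with exact accounting
#'
#' Rule order is fixed: (1) non-standard views are dropped record-wise;
#' then, per examination (or per record when `exam_level = FALSE`):
#' (2) compression force 0 N or above `cf_max`, (3) tube loading in
#' `[0, mas_min)`, (4) 0 kVp, (5) thickness above `cbt_max`,
#' (6) implant present. Each removed examination is attributed to the first
#' rule that triggered, so the report counts sum exactly to the records
#' removed.
#'
#' @param table a [cohort_table()].
#' @param cfg a [filter_config()].
#' @return List with `cohort` (filtered [cohort_table()]) and `report`
#'   (a `filter_report`: `n_in`, `n_out`, `removed_by_rule` in record
#'   counts, `exams_removed_by_rule`, `rule_order`, `warnings`).
#' @export
apply_exclusions <- function(table, cfg = filter_config()) {
  stopifnot(inherits(table, "cohort_table"), inherits(cfg, "filter_config"))
  n_in <- nrow(table)
  removed_rec <- setNames(integer(length(FILTER_RULES)), FILTER_RULES)
  removed_exam <- removed_rec

  bad_view <- !(table$view %in% cfg$allowed_views)
  removed_rec["non_standard_view"] <- sum(bad_view)
  kept <- as.data.frame(table)[!bad_view, , drop = FALSE]

  viol <- function(df) {
    m <- cbind(
      compression_force =
        (!is.na(df$compression_force)) &
          (df$compression_force > cfg$cf_max |
             (cfg$cf_exclude_zero & df$compression_force == 0)),
      low_mas = (!is.na(df$mas)) & df$mas >= 0 & df$mas < cfg$mas_min,
      zero_kvp = cfg$kvp_exclude_zero & (!is.na(df$kvp)) & df$kvp == 0,
      cbt_above_max = (!is.na(df$cbt)) & df$cbt > cfg$cbt_max,
      implant_present = cfg$exclude_implants &
        (!is.na(df$implant_present)) & df$implant_present
    )
    m
  }

  if (nrow(kept)) {
    vm <- viol(kept)
    rule_names <- colnames(vm)
    if (cfg$exam_level) {
      key <- paste(kept$center_id, kept$exam_id, sep = "\r")
      fkey <- factor(key, levels = unique(key))
      # first violated rule per exam: any view violating removes the exam
      exam_viol <- rowsum(vm + 0, fkey, reorder = FALSE) > 0
      first_rule <- apply(exam_viol, 1L, function(r)
        if (any(r)) which(r)[1] else NA_integer_)
      exam_sizes <- tabulate(fkey)
      drop_exam <- !is.na(first_rule)
      for (i in which(drop_exam)) {
        rn <- rule_names[first_rule[i]]
        removed_exam[rn] <- removed_exam[rn] + 1L
        removed_rec[rn] <- removed_rec[rn] + exam_sizes[i]
      }
      kept <- kept[!drop_exam[as.integer(fkey)], , drop = FALSE]
    } else {
      first_rule <- apply(vm, 1L, function(r)
        if (any(r)) which(r)[1] else NA_integer_)
      for (i in which(!is.na(first_rule))) {
        rn <- rule_names[first_rule[i]]
        removed_rec[rn] <- removed_rec[rn] + 1L
      }
      kept <- kept[is.na(first_rule), , drop = FALSE]
    }
  }

  out <- cohort_table(kept, provenance = paste0(
    attr(table, "provenance"), " | filtered"))
  warnings <- character(0)
  if (nrow(out) == 0L) warnings <- "no records remain after exclusions"
  report <- structure(list(
    n_in = n_in, n_out = nrow(out),
    removed_by_rule = as.list(removed_rec),
    exams_removed_by_rule = as.list(removed_exam),
    rule_order = FILTER_RULES,
    exam_level = cfg$exam_level,
    warnings = warnings), class = "filter_report")
  stopifnot(report$n_out == report$n_in - sum(removed_rec))
  list(cohort = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d records in, %d out (%s-level rules)\n",
              x$n_in, x$n_out, if (x$exam_level) "examination" else "record"))
  for (rn in x$rule_order) {
    cat(sprintf("  %-18s %6d records  %5d exams\n", rn,
                x$removed_by_rule[[rn]], x$exams_removed_by_rule[[rn]]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Serialize a filter report as JSON
#' @param report a `filter_report`.
#' @param path output path; if `NULL`, returns the JSON string.
#' @export
write_filter_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  j <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}
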