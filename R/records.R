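#' Construct a cohort table of mammographic exposure records
#'
#' A cohort table is a data frame with one row per exposure (one acquired
#' view), carrying the exposure factors, patient descriptors and the
#' unit-reported average glandular dose (AGD, the DICOM "Organ Dose").
#' Records failing basic validity (negative dose, thickness, mAs, kVp or
#' compression force, or a non-finite mandatory field) are dropped and
#' counted in the provenance attribute; the examination-level survey
#' exclusions live in [apply_exclusions()], not here.
#'
#' @param records data frame containing (a subset of) the canonical columns
#'   `center_id`, `exam_id`, `patient_age`, `view`, `laterality`, `cbt` (mm),
#'   `mas`, `kvp`, `compression_force` (N), `implant_present`, `agd` (mGy),
#'   `exposure_control_mode`, `anode_target`, `filter_material`,
#'   `manufacturer`, `model_name`. Missing descriptive columns are filled
#'   with `NA`; `view`, `cbt` and `agd` are mandatory per record.
#' @param provenance character scalar describing the source.
#' @return A `cohort_table`: a data frame with canonical columns and
#'   attributes `provenance` and `n_dropped` (records removed during
#'   validation).
#' @export
cohort_table <- function(records, provenance = "in-memory") {
  stopifnot(is.data.frame(records))
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(COHORT_COLUMNS, names(df))) {
    fill <- if (col %in% COHORT_NUMERIC) NA_real_
            else if (col == "implant_present") NA
            else NA_character_
    df[[col]] <- rep(fill, nrow(df))
  }
  df <- df[COHORT_COLUMNS]
  for (col in COHORT_NUMERIC) df[[col]] <- as.numeric(df[[col]])
  for (col in c("center_id", "exam_id", "view", "laterality")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$view <- toupper(trimws(df$view))
  df$laterality <- toupper(trimws(df$laterality))
  df$implant_present <- as.logical(df$implant_present)

  # mandatory fields + non-negativity of physical quantities
  ok <- !is.na(df$view) & df$view != "" & !is.na(df$cbt) & !is.na(df$agd)
  for (col in c("agd", "cbt", "kvp", "mas", "compression_force")) {
    ok <- ok & (is.na(df[[col]]) | df[[col]] >= 0)
  }
  dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            provenance = provenance,
            n_dropped = dropped,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d records, %d centers, %d exams\n",
              nrow(x), length(unique(x$center_id)),
              nrow(unique(x[c("center_id", "exam_id")]))))
  cat("  provenance:", attr(x, "provenance"), "\n")
  if (isTRUE(attr(x, "n_dropped") > 0)) {
    cat("  dropped during validation:", attr(x, "n_dropped"), "\n")
  }
  if (nrow(x)) print(head(as.data.frame(x), 5L))
  invisible(x)
}

#' Column-name dialect for CSV cohort files
#'
#' Maps the canonical record fields to the column names used by a particular
#' export (for example `BodyPartThickness` for `cbt`). Fields not present in
#' the file are marked absent by omitting them from the mapping.
#'
#' @param ... named character entries, canonical field = file column name.
#' @param agd_unit unit of the dose column in the file: one of `"mGy"`
#'   (default for CSV exports), `"dGy"`, `"Gy"`, `"uGy"`.
#' @return A named list of class `csv_dialect`.
#' @export
csv_dialect <- function(..., agd_unit = "mGy") {
  map <- list(...)
  if (length(map) == 1L && is.list(map[[1]]) && is.null(names(map))) {
    map <- map[[1]]
  }
  bad <- setdiff(names(map), COHORT_COLUMNS)
  if (length(bad)) stop("unknown record fields in dialect: ",
                        paste(bad, collapse = ", "))
  structure(list(map = map, agd_unit = match.arg(agd_unit,
              c("mGy", "dGy", "Gy", "uGy"))), class = "csv_dialect")
}

#' Read a CSV column-dialect mapping from a YAML file
#'
#' The YAML file holds `columns:` (canonical field -> file column name) and
#' optionally `agd_unit:`.
#'
#' @param path YAML file path.
#' @return A `csv_dialect`.
#' @export
read_dialect <- function(path) {
  y <- yaml::read_yaml(path)
  csv_dialect(y$columns %||% list(),
              agd_unit = y$agd_unit %||% "mGy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

agd_unit_factor <- function(unit) {
  switch(unit, mGy = 1, dGy = 100, Gy = 1000, uGy = 1e-3,
         stop("unknown AGD unit: ", unit))
}

#' Read exposure records from a CSV file
#'
#' The file must have a header row. Canonical column names are used directly;
#' a [csv_dialect()] renames non-canonical columns and declares the dose
#' unit. Rows whose mandatory numeric cells do not parse are dropped and
#' counted in the provenance.
#'
#' @param path CSV file path.
#' @param dialect optional [csv_dialect()].
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(dialect)) {
    stopifnot(inherits(dialect, "csv_dialect"))
    for (field in names(dialect$map)) {
      src <- dialect$map[[field]]
      if (!src %in% names(raw)) {
        stop("schema error: mapped column '", src, "' (field '", field,
             "') not present in ", path)
      }
      names(raw)[names(raw) == src] <- field
    }
  }
  missing_mand <- setdiff(c("view", "cbt", "agd"), names(raw))
  if (length(missing_mand)) {
    stop("schema error: mandatory column(s) missing: ",
         paste(missing_mand, collapse = ", "))
  }
  keep <- intersect(COHORT_COLUMNS, names(raw))
  df <- raw[keep]
  n_bad <- 0L
  for (col in intersect(COHORT_NUMERIC, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & df[[col]] != "" & is.na(v)
    n_bad <- n_bad + 0L  # counted row-wise below
    df[[col]] <- ifelse(bad, NaN, v)
  }
  bad_row <- Reduce(`|`, lapply(df[intersect(COHORT_NUMERIC, names(df))],
                                is.nan), rep(FALSE, nrow(df)))
  df <- df[!bad_row, , drop = FALSE]
  if ("implant_present" %in% names(df)) {
    v <- toupper(trimws(df$implant_present))
    df$implant_present <- ifelse(is.na(v) | v == "", NA,
                                 v %in% c("TRUE", "YES", "1", "T", "Y"))
  }
  if (!is.null(dialect) && "agd" %in% names(df)) {
    df$agd <- as.numeric(df$agd) * agd_unit_factor(dialect$agd_unit)
  }
  tab <- cohort_table(df, provenance = sprintf(
    "csv:%s (parsed %s)", path, format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  attr(tab, "n_dropped") <- attr(tab, "n_dropped") + sum(bad_row)
  tab
}

#' Write a cohort table as canonical CSV
#'
#' Deterministic column order (the canonical order), header row, full
#' double precision for numeric fields. Round-trips losslessly through
#' [read_cohort_csv()].
#'
#' @param table a [cohort_table()].
#' @param path output file path.
#' @param force write even if the table is empty.
#' @export
write_cohort_csv <- function(table, path, force = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) == 0L && !force) {
    stop("refusing to write an empty cohort table (use force = TRUE)")
  }
  df <- as.data.frame(table)[COHORT_COLUMNS]
  for (col in COHORT_NUMERIC) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE,
                                   trim = TRUE)
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
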