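#' Pipeline run configuration
#'
#' @param input path to a cohort CSV, or `NULL` to simulate a cohort with
#'   [generate_cohort()].
#' @param dialect optional [csv_dialect()] for the input file.
#' @param synth a [synth_config()] used when `input` is `NULL`.
#' @param filter a [filter_config()].
#' @param bins a [bin_scheme()].
#' @param families model families to fit.
#' @param views views to analyse.
#' @param percentile_type DRL percentile convention.
#' @param simplest_cbt,simplest_half_width typical-thickness window, mm.
#' @param stratify_by optional record field (e.g. `"manufacturer"`) for
#'   stratified curve fits.
#' @param limits optional [limit_curves()] for classification.
#' @param seed integer seed for fitting (and simulation, if no input file).
#' @param output_dir run directory (created).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, dialect = NULL, synth = synth_config(),
                       filter = filter_config(), bins = bin_scheme(),
                       families = MODEL_FAMILIES, views = c("CC", "MLO"),
                       percentile_type = "linear",
                       simplest_cbt = 50, simplest_half_width = 5,
                       stratify_by = NULL, limits = NULL,
                       seed = 1L, output_dir = tempfile("drl_run_")) {
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input)
  }
  structure(list(input = input, dialect = dialect, synth = synth,
                 filter = filter, bins = bins, families = families,
                 views = toupper(views), percentile_type = percentile_type,
                 simplest_cbt = simplest_cbt,
                 simplest_half_width = simplest_half_width,
                 stratify_by = stratify_by, limits = limits,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Most populated thickness window
#'
#' Slides an integer-centered window of the given width (half-open,
#' `[c - width/2, c + width/2)`) over the observed thickness range and
#' returns the center with the highest record count; ties go to the lowest
#' center. This is the data-driven "typical CBT" of the cohort.
#'
#' @param table a [cohort_table()].
#' @param width window width, mm.
#' @return List `center` (mm) and `count`.
#' @export
modal_cbt_window <- function(table, width = 10) {
  stopifnot(inherits(table, "cohort_table"))
  cbt <- table$cbt[!is.na(table$cbt)]
  if (length(cbt) == 0L) stop("cohort has no thickness values")
  centers <- seq(ceiling(min(cbt)), max(floor(max(cbt)), ceiling(min(cbt))))
  half <- width / 2
  counts <- vapply(centers, function(cc)
    sum(cbt >= cc - half & cbt < cc + half), numeric(1))
  best <- which.max(counts)  # which.max takes the first (lowest) maximum
  list(center = centers[best], count = as.integer(counts[best]))
}

pipeline_plots <- function(cohort, binned, comparisons, cfg, fig_dir) {
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  # per-bin DRL bars, both views
  bar_df <- do.call(rbind, lapply(names(binned), function(v) {
    b <- binned[[v]]
    data.frame(view = v,
               bin = sprintf("%g-%g", b$bin_lo, b$bin_hi),
               mid = (b$bin_lo + b$bin_hi) / 2, drl = b$drl)
  }))
  p1 <- ggplot2::ggplot(bar_df,
          ggplot2::aes(x = factor(mid), y = drl, fill = view)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "CBT bin center [mm]", y = "DRL [mGy]",
                  title = "DRL per 10-mm CBT range") +
    ggplot2::theme_minimal()
  save_plot(p1, file.path(fig_dir, "drl_per_bin.pdf"))

  modal <- modal_cbt_window(cohort)
  p2 <- ggplot2::ggplot(as.data.frame(cohort), ggplot2::aes(x = cbt)) +
    ggplot2::geom_histogram(binwidth = 2, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = modal$center + c(-5, 5),
                        linetype = "dashed") +
    ggplot2::labs(x = "CBT [mm]", y = "records",
                  title = sprintf(
                    "CBT distribution (modal 10-mm window: %g +/- 5 mm)",
                    modal$center)) +
    ggplot2::theme_minimal()
  save_plot(p2, file.path(fig_dir, "cbt_distribution.pdf"))

  for (v in names(comparisons)) {
    g <- comparisons[[v]]$grid
    long <- rbind(
      data.frame(cbt = g$cbt, drl = g$eq_drl, approach = "equation"),
      data.frame(cbt = g$cbt, drl = g$range_drl, approach = "10-mm range"))
    p3 <- ggplot2::ggplot(long,
            ggplot2::aes(x = cbt, y = drl, colour = approach)) +
      ggplot2::geom_step(data = long[long$approach == "10-mm range", ]) +
      ggplot2::geom_line(data = long[long$approach == "equation", ]) +
      ggplot2::labs(x = "CBT [mm]", y = "DRL [mGy]",
                    title = sprintf("Step vs curve DRL, %s view", v)) +
      ggplot2::theme_minimal()
    if (!is.null(cfg$limits)) {
      lim_long <- rbind(
        cbind(cfg$limits$acceptable, which = "acceptable"),
        cbind(cfg$limits$achievable, which = "achievable"))
      p3 <- p3 + ggplot2::geom_line(
        data = lim_long,
        ggplot2::aes(x = cbt_mm, y = mGy, linetype = which),
        colour = "black", inherit.aes = FALSE)
    }
    save_plot(p3, file.path(fig_dir, sprintf("step_vs_curve_%s.pdf", v)))
  }
  invisible(NULL)
}

save_plot <- function(p, path) {
  grDevices::pdf(path, width = 7, height = 4.5)
  print(p)
  grDevices::dev.off()
}

#' Run the full DRL pipeline
#'
#' Ingest (or simulate), filter with accounting, estimate the three DRL
#' flavours per view, fit and rank the model families, compare the
#' approaches, optionally classify against limit curves and stratify curve
#' fits by a record field, and write all artifacts plus a machine-readable
#' manifest capturing every convention (percentile type, bin scheme,
#' seeds, boundary conventions).
#'
#' Any stage failure is recorded in the manifest (`failed_at`) with the
#' partial outputs retained on disk.
#'
#' @param cfg a [run_config()].
#' @return The run directory path, invisibly; the manifest as attribute
#'   `manifest`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mammodrl")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    input = cfg$input %||% "simulated",
    views = cfg$views,
    percentile_type = cfg$percentile_type,
    bin_breaks = cfg$bins$breaks,
    bin_representative = cfg$bins$representative,
    bin_convention = "half-open [lo, hi) bins; last bin closed",
    mas_boundary = "half-open [0, mas_min) excluded",
    cbt_boundary = "strictly above cbt_max excluded",
    simplest_window = c(cfg$simplest_cbt - cfg$simplest_half_width,
                        cfg$simplest_cbt + cfg$simplest_half_width),
    families = cfg$families,
    filter = unclass(cfg$filter),
    stratify_by = cfg$stratify_by %||% "none",
    failed_at = NA)
  finish <- function() {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, na = "null"),
               file.path(out, "manifest.json"))
    structure(invisible(out), manifest = manifest)
  }
  stage <- "ingest"
  res <- tryCatch({
    if (is.null(cfg$input)) {
      synth <- cfg$synth
      synth$seed <- cfg$seed
      gen <- generate_cohort(synth)
      cohort <- gen$cohort
      manifest$synth <- list(
        n_centers = synth$n_centers,
        exams_per_center = synth$exams_per_center,
        contamination = synth$contamination)
    } else {
      cohort <- read_cohort_csv(cfg$input, cfg$dialect)
    }
    write_cohort_csv(cohort, file.path(out, "cohort_raw.csv"))

    stage <- "filter"
    fl <- apply_exclusions(cohort, cfg$filter)
    write_filter_report(fl$report, file.path(out, "filter_report.json"))
    writeLines(utils::capture.output(print(fl$report)),
               file.path(out, "filter_report.txt"))
    cohort <- fl$cohort
    if (nrow(cohort) == 0L) stop("no records remain after exclusions")

    stage <- "estimate"
    binned <- list(); fits <- list(); curves <- list(); comps <- list()
    simplest <- list()
    for (v in cfg$views) {
      b <- binned_drl_table(cohort, v, cfg$bins,
                            type = cfg$percentile_type)
      binned[[v]] <- b
      write_binned_drl(b, file.path(out, sprintf("binned_drl_%s.csv", v)))
      write_binned_drl(b, file.path(out, sprintf("binned_drl_%s.json", v)))
      simplest[[v]] <- tryCatch(
        simplest_drl(cohort, v, cfg$simplest_cbt, cfg$simplest_half_width,
                     type = cfg$percentile_type),
        error = function(e) NA_real_)

      stage <- "fit"
      fa <- fit_all(b, cfg$families, seed = cfg$seed)
      fits[[v]] <- fa$fits
      curves[[v]] <- fa$curve
      write_curve_json(fa$curve, fa$fits,
                       file.path(out, sprintf("curve_%s.json", v)))

      stage <- "compare"
      comp <- compare_equation_vs_ranges(
        fa$curve, b, simplest = if (is.na(simplest[[v]])) NULL
                                else simplest[[v]])
      comps[[v]] <- comp
      write_comparison(comp, file.path(out, sprintf("comparison_%s.csv", v)))
      write_comparison(comp, file.path(out, sprintf("comparison_%s.json", v)))
      if (!is.null(cfg$limits)) {
        cl <- classify_against_limits(fa$curve, cfg$limits)
        utils::write.csv(cl$grid,
                         file.path(out, sprintf("limits_%s.csv", v)),
                         row.names = FALSE)
        manifest$limit_regions[[v]] <- cl$regions
      }
    }
    manifest$simplest_drl <- simplest
    manifest$n_bins <- as.list(vapply(binned, nrow, integer(1)))
    manifest$n_fits <- as.list(vapply(fits, length, integer(1)))
    manifest$selected_family <-
      as.list(vapply(curves, function(cu) cu$fit$family, character(1)))
    manifest$equations <-
      as.list(vapply(curves, equation_string, character(1)))

    if (!is.null(cfg$stratify_by)) {
      stage <- "stratify"
      strata <- unique(as.data.frame(cohort)[[cfg$stratify_by]])
      strata <- strata[!is.na(strata)]
      manifest$strata <- as.character(strata)
      for (s in strata) {
        sub <- cohort[as.data.frame(cohort)[[cfg$stratify_by]] == s, ,
                      drop = FALSE]
        sub <- cohort_table(as.data.frame(sub),
                            provenance = paste0("stratum:", s))
        for (v in cfg$views) {
          bs <- binned_drl_table(sub, v, cfg$bins,
                                 type = cfg$percentile_type)
          fa_s <- tryCatch(fit_all(bs, cfg$families, seed = cfg$seed),
                           error = function(e) NULL)
          if (!is.null(fa_s)) {
            write_curve_json(fa_s$curve, fa_s$fits, file.path(
              out, sprintf("curve_%s_%s.json", v, gsub("\\W", "_", s))))
          }
        }
      }
    }

    stage <- "plots"
    pipeline_plots(cohort, binned, comps, cfg, file.path(out, "figures"))
    TRUE
  }, error = function(e) {
    manifest$failed_at <<- stage
    manifest$error <<- conditionMessage(e)
    FALSE
  })
  finish()
}
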