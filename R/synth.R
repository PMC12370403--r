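# Synthetic multi-center screening cohorts with a known ground-truth DRL
# surface.  The generator is statistical, not dosimetric: dose noise is
# multiplicative lognormal with median 1, so the per-center median AGD at
# thickness t is exactly truth(t) * center_factor and the implied DRL curve
# has a closed form (see analytic_drl()).

# Per-center examination weights shaped like a national screening program:
# six high-volume centers and three small ones.
SYNTH_CENTER_WEIGHTS <- c(38028, 31092, 24000, 60899, 15584, 16321,
                          628, 493, 660)

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a national mammography screening survey: nine centers
#' of very different volume; compressed breast thickness truncated-normal
#' 58 +/- 12 mm on [13, 100]; patient age truncated-normal 50 +/- 8 y on
#' [30, 90]; a ground-truth median-dose curve rising steeply with CBT
#' (bi-exponential, amplitudes in mGy); MLO doses a constant factor above
#' CC; lognormal center-to-center and record-to-record dose variation; and
#' a small fraction of examinations containing one erroneous record
#' (compression force 0 or 250 N, mAs below 10, 0 kVp, or CBT above
#' 100 mm) to exercise the exclusion rules.
#'
#' @param n_centers number of centers.
#' @param exams_per_center integer vector (recycled/truncated to
#'   `n_centers`) of examinations per center. Default: the screening-program
#'   weight profile scaled by `size_factor`.
#' @param size_factor scale applied to the default weights (default 0.05,
#'   about 9400 examinations, 37,500 records).
#' @param cbt_mean,cbt_sd,cbt_bounds CBT distribution (mm).
#' @param age_mean,age_sd,age_bounds age distribution (years).
#' @param truth_cc bi-exponential coefficients `c(a, b, c, d)` of the CC
#'   median-dose curve `a*exp(b*t) + c*exp(d*t)` (mGy; rates 1/mm). The
#'   default uses amplitudes 0.94 and 7.30e-4 mGy with time constants
#'   118.65 and 15.85 mm, a published national DRL-curve shape.
#' @param mlo_factor multiplicative MLO/CC median-dose ratio.
#' @param center_log_sd lognormal sd of the per-center dose factor.
#' @param record_log_sd lognormal sd of per-record dose noise.
#' @param contamination fraction of examinations given one rule-violating
#'   record.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_centers = 9L,
                         exams_per_center = NULL,
                         size_factor = 0.05,
                         cbt_mean = 58, cbt_sd = 12, cbt_bounds = c(13, 100),
                         age_mean = 50, age_sd = 8, age_bounds = c(30, 90),
                         truth_cc = c(a = 0.94, b = 1 / 118.65,
                                      c = 7.30e-4, d = 1 / 15.85),
                         mlo_factor = 1.12,
                         center_log_sd = 0.10,
                         record_log_sd = 0.25,
                         contamination = 0.01,
                         seed = 1L) {
  if (is.null(exams_per_center)) {
    exams_per_center <- pmax(1L, as.integer(round(
      rep_len(SYNTH_CENTER_WEIGHTS, n_centers) * size_factor)))
  } else {
    exams_per_center <- as.integer(rep_len(exams_per_center, n_centers))
  }
  cfg <- list(n_centers = as.integer(n_centers),
              exams_per_center = exams_per_center,
              cbt_mean = cbt_mean, cbt_sd = cbt_sd, cbt_bounds = cbt_bounds,
              age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
              truth_cc = truth_cc, mlo_factor = mlo_factor,
              center_log_sd = center_log_sd, record_log_sd = record_log_sd,
              contamination = contamination, seed = as.integer(seed))
  problems <- character(0)
  if (!(cfg$cbt_sd > 0)) problems <- c(problems, "cbt_sd must be > 0")
  if (!(cfg$age_sd > 0)) problems <- c(problems, "age_sd must be > 0")
  if (!(cfg$record_log_sd > 0)) {
    problems <- c(problems, "record_log_sd must be > 0")
  }
  if (cfg$center_log_sd < 0) {
    problems <- c(problems, "center_log_sd must be >= 0")
  }
  if (diff(cfg$cbt_bounds) <= 0 || diff(cfg$age_bounds) <= 0) {
    problems <- c(problems, "distribution bounds must be ordered")
  }
  if (cfg$contamination < 0 || cfg$contamination > 0.5) {
    problems <- c(problems, "contamination must lie in [0, 0.5]")
  }
  if (length(problems)) {
    stop("invalid synth_config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "synth_config")
}

# inverse-CDF sampler for a truncated normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

truth_curve <- function(cfg, view, cbt) {
  p <- unname(cfg$truth_cc)
  v <- p[1] * exp(p[2] * cbt) + p[3] * exp(p[4] * cbt)
  if (toupper(view) == "MLO") v * cfg$mlo_factor else v
}

#' Generate a synthetic multi-center cohort
#'
#' Each examination contributes four records (CC/MLO x L/R); the two views
#' of one breast share a single CBT draw. AGD is
#' `truth(view, cbt) * center_factor * exp(N(0, record_log_sd))`. Exposure
#' factors are drawn within plausible clinical ranges that never trigger
#' the exclusion rules, so the only rule-violating records are the
#' deliberately contaminated ones: a `contamination` fraction of
#' examinations gets one record with a violation drawn uniformly over the
#' rule types (CF 0 N, CF 250 N, 5 mAs, 0 kVp, CBT 105 mm).
#'
#' @param cfg a [synth_config()].
#' @return List `cohort` (a [cohort_table()]) and `truth` (a
#'   `synth_ground_truth`: the median curve parameters, per-center factors,
#'   contaminated exam ids, and the config).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_private_seed(cfg$seed, {
    center_factors <- setNames(
      exp(rnorm(cfg$n_centers, 0, cfg$center_log_sd)),
      sprintf("C%02d", seq_len(cfg$n_centers)))
    manufacturers <- c("VendorA", "VendorB", "VendorC")
    center_vendor <- manufacturers[(seq_len(cfg$n_centers) - 1L) %% 3L + 1L]

    per_center <- lapply(seq_len(cfg$n_centers), function(ci) {
      ne <- cfg$exams_per_center[ci]
      cid <- names(center_factors)[ci]
      exam_id <- sprintf("%s-E%06d", cid, seq_len(ne))
      age <- round(rtruncnorm(ne, cfg$age_mean, cfg$age_sd,
                              cfg$age_bounds[1], cfg$age_bounds[2]))
      # one CBT per breast, shared by its CC and MLO acquisitions
      cbt_l <- rtruncnorm(ne, cfg$cbt_mean, cfg$cbt_sd,
                          cfg$cbt_bounds[1], cfg$cbt_bounds[2])
      cbt_r <- rtruncnorm(ne, cfg$cbt_mean, cfg$cbt_sd,
                          cfg$cbt_bounds[1], cfg$cbt_bounds[2])
      view <- rep(c("CC", "CC", "MLO", "MLO"), ne)
      lat <- rep(c("L", "R", "L", "R"), ne)
      cbt <- as.vector(rbind(cbt_l, cbt_r, cbt_l, cbt_r))
      n_rec <- 4L * ne
      agd <- truth_curve(cfg, "CC", cbt) *
        ifelse(view == "MLO", cfg$mlo_factor, 1) *
        center_factors[ci] * exp(rnorm(n_rec, 0, cfg$record_log_sd))
      data.frame(
        center_id = cid,
        exam_id = rep(exam_id, each = 4L),
        patient_age = rep(age, each = 4L),
        view = view, laterality = lat, cbt = cbt,
        mas = rtruncnorm(n_rec, 74, 31, 11, 404),
        kvp = round(rtruncnorm(n_rec, 29, 1, 23, 40)),
        compression_force = round(rtruncnorm(n_rec, 135, 37, 20, 200)),
        implant_present = FALSE,
        agd = agd,
        exposure_control_mode = "AUTO_FILTER",
        anode_target = "W", filter_material = "Rh",
        manufacturer = center_vendor[ci],
        model_name = paste0(center_vendor[ci], "-M1"),
        stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_center)

    exams <- unique(df$exam_id)
    contaminated <- exams[runif(length(exams)) < cfg$contamination]
    if (length(contaminated)) {
      rule_vals <- list(
        function(df, i) { df$compression_force[i] <- 0; df },
        function(df, i) { df$compression_force[i] <- 250; df },
        function(df, i) { df$mas[i] <- 5; df },
        function(df, i) { df$kvp[i] <- 0; df },
        function(df, i) { df$cbt[i] <- 105; df })
      which_rule <- sample.int(length(rule_vals), length(contaminated),
                               replace = TRUE)
      first_row <- match(contaminated, df$exam_id)
      for (k in seq_along(contaminated)) {
        i <- first_row[k] + sample.int(4L, 1L) - 1L
        df <- rule_vals[[which_rule[k]]](df, i)
      }
    }

    truth <- structure(list(
      truth_cc = cfg$truth_cc,
      mlo_factor = cfg$mlo_factor,
      center_factors = center_factors,
      contaminated_exams = contaminated,
      config = cfg), class = "synth_ground_truth")
    cohort <- cohort_table(df, provenance = sprintf(
      "synthetic cohort (seed %d, %d centers, %d exams)",
      cfg$seed, cfg$n_centers, sum(cfg$exams_per_center)))
    list(cohort = cohort, truth = truth)
  })
}

#' Closed-form DRL implied by the synthetic generative model
#'
#' Because record noise is multiplicative with median 1, the per-center
#' median dose at thickness `t` is `truth(view, t) * center_factor`, so the
#' 75th percentile of center medians is `truth(view, t)` times the 75th
#' percentile of the center factors - no sampling needed.
#'
#' @param truth a `synth_ground_truth` from [generate_cohort()].
#' @param view `"CC"` or `"MLO"`.
#' @param cbt thickness vector, mm.
#' @param type percentile convention, see [drl_percentile()].
#' @return Analytic DRL values, mGy.
#' @export
analytic_drl <- function(truth, view, cbt,
                         type = c("linear", "nearest_rank")) {
  stopifnot(inherits(truth, "synth_ground_truth"))
  q75 <- drl_percentile(truth$center_factors, type = match.arg(type))
  truth_curve(truth$config, view, cbt) * q75
}

#' Export a synthetic cohort as header-only DICOM files
#'
#' Writes one DICOM Part-10 stub per record (see [write_dicom_stub()]),
#' with Organ Dose stored in dGy per the DICOM attribute definition.
#'
#' @param cohort a [cohort_table()].
#' @param dir output directory (created if needed).
#' @param max_files safety cap on the number of files written.
#' @return Character vector of paths written.
#' @export
export_dicom_stubs <- function(cohort, dir, max_files = 1000L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort) > max_files) {
    stop("cohort has ", nrow(cohort), " records; raise max_files to write")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    p <- file.path(dir, sprintf("rec%05d.dcm", i))
    write_dicom_stub(p, list(
      modality = "MG",
      institution = r$center_id,
      accession = r$exam_id,
      patient_id = sub("-E.*", "-P", r$exam_id),
      patient_age = sprintf("%03dY", as.integer(r$patient_age)),
      view_position = r$view,
      laterality = r$laterality,
      body_part_thickness = format(r$cbt, digits = 10),
      exposure_mas = as.character(round(r$mas)),
      kvp = format(r$kvp, digits = 10),
      compression_force = format(r$compression_force, digits = 10),
      implant_present = if (isTRUE(r$implant_present)) "YES" else "NO",
      organ_dose = format(r$agd / 100, digits = 10),  # mGy -> dGy
      exposure_control = r$exposure_control_mode,
      anode_target = r$anode_target,
      filter_material = r$filter_material,
      manufacturer = r$manufacturer,
      model_name = r$model_name))
    paths[i] <- p
  }
  paths
}
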