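# Minimal DICOM Part-10 support, explicit-VR little-endian only.
#
# Scope: read the metadata attributes needed for a dose survey from file
# headers (never the pixel data), and write small header-only files so the
# extraction path is testable without patient data.  Sequences and implicit
# VR are out of scope; unreadable files are reported, not fatal.

# (group, element, VR) of every attribute the extractor uses.
DICOM_TAGS <- list(
  media_sop_class    = c(0x0002, 0x0002, "UI"),
  media_sop_instance = c(0x0002, 0x0003, "UI"),
  transfer_syntax    = c(0x0002, 0x0010, "UI"),
  implementation_uid = c(0x0002, 0x0012, "UI"),
  study_date         = c(0x0008, 0x0020, "DA"),
  accession          = c(0x0008, 0x0050, "SH"),
  modality           = c(0x0008, 0x0060, "CS"),
  manufacturer       = c(0x0008, 0x0070, "LO"),
  institution        = c(0x0008, 0x0080, "LO"),
  model_name         = c(0x0008, 0x1090, "LO"),
  patient_id         = c(0x0010, 0x0020, "LO"),
  patient_age        = c(0x0010, 0x1010, "AS"),
  kvp                = c(0x0018, 0x0060, "DS"),
  exposure_mas       = c(0x0018, 0x1152, "IS"),
  anode_target       = c(0x0018, 0x1191, "CS"),
  view_position      = c(0x0018, 0x5101, "CS"),
  filter_material    = c(0x0018, 0x7050, "CS"),
  exposure_control   = c(0x0018, 0x7060, "CS"),
  body_part_thickness = c(0x0018, 0x11A0, "DS"),
  compression_force  = c(0x0018, 0x11A2, "DS"),
  study_uid          = c(0x0020, 0x000D, "UI"),
  laterality         = c(0x0020, 0x0062, "CS"),
  implant_present    = c(0x0028, 0x1300, "CS"),
  organ_dose         = c(0x0040, 0x0316, "DS")
)

EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
uint32 <- function(raw4) {
  sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))
}

#' Read the header attributes of one DICOM file
#'
#' Parses a Part-10 explicit-VR little-endian file up to (and excluding) the
#' PixelData element; the pixel payload is never read, so truncated or
#' header-only files parse fine.
#'
#' @param path file path.
#' @return Named list of attribute values (character), using the internal
#'   attribute names of the survey extractor.
#' @export
read_dicom_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L ||
      rawToChar(preamble[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file: ", path)
  }
  out <- list()
  repeat {
    hdr <- readBin(con, "raw", 8L)
    if (length(hdr) < 8L) break
    group <- uint16(hdr[1:2]); elem <- uint16(hdr[3:4])
    vr <- rawToChar(hdr[5:6])
    if (group == 0x7FE0 && elem == 0x0010) break  # stop before pixel data
    if (vr %in% dicom_long_vrs) {
      len_raw <- readBin(con, "raw", 4L)
      len <- uint32(len_raw)
      if (vr == "SQ" || len == 0xFFFFFFFF) {
        break  # undefined-length sequences unsupported; header part done
      }
    } else {
      len <- uint16(hdr[7:8])
    }
    val <- readBin(con, "raw", len)
    if (length(val) < len) break
    key <- dicom_key(group, elem)
    if (!is.null(key)) {
      out[[key]] <- trimws(rawToChar(val[val != as.raw(0)]))
    }
  }
  out
}

dicom_key <- function(group, elem) {
  for (nm in names(DICOM_TAGS)) {
    t <- DICOM_TAGS[[nm]]
    if (as.integer(t[1]) == group && as.integer(t[2]) == elem) return(nm)
  }
  NULL
}

encode_element <- function(group, elem, vr, value) {
  value <- as.character(value)
  pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
  v <- charToRaw(value)
  if (length(v) %% 2L == 1L) v <- c(v, pad)
  tag <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                  size = 2, endian = "little")
  if (vr %in% dicom_long_vrs) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(v), raw(), size = 4, endian = "little"), v)
  } else {
    c(tag, charToRaw(vr),
      writeBin(length(v), raw(), size = 2, endian = "little"), v)
  }
}

#' Write a minimal header-only DICOM file
#'
#' Produces a valid Part-10 explicit-VR little-endian file containing the
#' given survey attributes and no pixel data. Intended for fixtures and for
#' exporting synthetic cohorts in DICOM form.
#'
#' @param path output path.
#' @param attrs named list: any of the names in the internal tag dictionary
#'   (e.g. `view_position`, `body_part_thickness`, `organ_dose`).
#' @param truncated_pixeldata if `TRUE`, append a PixelData element whose
#'   declared length exceeds the bytes actually written, emulating a
#'   truncated image; header extraction must still succeed.
#' @return `path`, invisibly.
#' @export
write_dicom_stub <- function(path, attrs, truncated_pixeldata = FALSE) {
  meta_attrs <- list(
    media_sop_class = "1.2.840.10008.5.1.4.1.1.1.2",
    media_sop_instance = paste0("1.2.826.0.1.", abs(sum(utf8ToInt(path)))),
    transfer_syntax = EXPLICIT_LE,
    implementation_uid = "1.2.826.0.1.3680043.9999.1"
  )
  meta_body <- raw(0)
  for (nm in names(meta_attrs)) {
    t <- DICOM_TAGS[[nm]]
    meta_body <- c(meta_body, encode_element(t[1], t[2], t[3],
                                             meta_attrs[[nm]]))
  }
  # FileMetaInformationVersion then group length ahead of the body
  ver <- c(writeBin(c(2L, 1L), raw(), size = 2, endian = "little"),
           charToRaw("OB"), as.raw(c(0, 0)),
           writeBin(2L, raw(), size = 4, endian = "little"),
           as.raw(c(0, 1)))
  meta_body <- c(ver, meta_body)
  grouplen <- c(writeBin(c(2L, 0L), raw(), size = 2, endian = "little"),
                charToRaw("UL"),
                writeBin(4L, raw(), size = 2, endian = "little"),
                writeBin(length(meta_body), raw(), size = 4,
                         endian = "little"))
  dataset_names <- setdiff(names(attrs), names(meta_attrs))
  ord <- order(vapply(dataset_names, function(nm) {
    t <- DICOM_TAGS[[nm]]
    as.integer(t[1]) * 65536 + as.integer(t[2])
  }, numeric(1)))
  body <- raw(0)
  for (nm in dataset_names[ord]) {
    t <- DICOM_TAGS[[nm]]
    if (is.null(t)) stop("unknown DICOM attribute name: ", nm)
    if (as.integer(t[1]) == 2L) next
    body <- c(body, encode_element(t[1], t[2], t[3], attrs[[nm]]))
  }
  if (truncated_pixeldata) {
    tag <- writeBin(c(0x7FE0L, 0x0010L), raw(), size = 2, endian = "little")
    body <- c(body, tag, charToRaw("OB"), as.raw(c(0, 0)),
              writeBin(1048576L, raw(), size = 4, endian = "little"),
              as.raw(rep(0, 16)))  # declared 1 MiB, 16 bytes present
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 128)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta_body, body), con)
  invisible(path)
}

#' Extract a cohort table from DICOM files
#'
#' Header-only extraction: one record per readable file. Files that cannot
#' be parsed are skipped and counted; records missing any of the mandatory
#' fields (view position, body part thickness, organ dose) or with a view
#' other than CC/MLO are dropped and counted. The DICOM Organ Dose attribute
#' (0040,0316) is defined in dGy and converted to mGy by default.
#'
#' @param paths character vector of file paths.
#' @param organ_dose_unit stored unit of Organ Dose: `"dGy"` (DICOM
#'   standard, default), or `"mGy"`, `"Gy"`, `"uGy"` for vendor dialects.
#' @return A [cohort_table()]; provenance records the path count, the number
#'   of unreadable files and the number of dropped records.
#' @export
extract_from_dicom <- function(paths, organ_dose_unit = "dGy") {
  if (length(paths) == 0L) stop("no input files given")
  factor <- agd_unit_factor(match.arg(organ_dose_unit,
                                      c("dGy", "mGy", "Gy", "uGy")))
  rows <- list(); unreadable <- 0L; dropped <- 0L
  for (p in paths) {
    hdr <- tryCatch(read_dicom_header(p), error = function(e) NULL)
    if (is.null(hdr)) { unreadable <- unreadable + 1L; next }
    view <- toupper(hdr$view_position %||% "")
    cbt <- suppressWarnings(as.numeric(hdr$body_part_thickness %||% NA))
    agd <- suppressWarnings(as.numeric(hdr$organ_dose %||% NA))
    if (!view %in% c("CC", "MLO") || is.na(cbt) || is.na(agd)) {
      dropped <- dropped + 1L; next
    }
    exam_id <- hdr$accession %||% hdr$study_uid %||%
      paste(hdr$institution %||% "?", hdr$patient_id %||% "?",
            hdr$study_date %||% "?", sep = "/")
    age <- hdr$patient_age
    age <- if (is.null(age)) NA_real_ else
      suppressWarnings(as.numeric(gsub("[^0-9]", "", age)))
    rows[[length(rows) + 1L]] <- data.frame(
      center_id = hdr$institution %||% NA_character_,
      exam_id = exam_id,
      patient_age = age,
      view = view,
      laterality = hdr$laterality %||% NA_character_,
      cbt = cbt,
      mas = suppressWarnings(as.numeric(hdr$exposure_mas %||% NA)),
      kvp = suppressWarnings(as.numeric(hdr$kvp %||% NA)),
      compression_force =
        suppressWarnings(as.numeric(hdr$compression_force %||% NA)),
      implant_present = identical(toupper(hdr$implant_present %||% ""),
                                  "YES"),
      agd = agd * factor,
      exposure_control_mode = hdr$exposure_control %||% NA_character_,
      anode_target = hdr$anode_target %||% NA_character_,
      filter_material = hdr$filter_material %||% NA_character_,
      manufacturer = hdr$manufacturer %||% NA_character_,
      model_name = hdr$model_name %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L && unreadable == length(paths)) {
    stop("none of the ", length(paths), " input files were readable DICOM")
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(view = character(), cbt = numeric(), agd = numeric())
  tab <- cohort_table(df, provenance = sprintf(
    "dicom:%d files (%d unreadable, %d dropped) %s",
    length(paths), unreadable, dropped,
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  attr(tab, "n_unreadable") <- unreadable
  attr(tab, "n_dropped") <- attr(tab, "n_dropped") + dropped
  tab
}
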