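#' Read an image series into an [image_volume()]
#'
#' A series is a directory holding a `series.json` metadata file plus NIfTI
#' voxel data: either one 3D file or one 2D file per slice, each slice entry
#' carrying its axial position. Slices are assembled in order of axial
#' position regardless of file order, the rescale slope/intercept from the
#' metadata is applied, and geometry and timestamps are populated from the
#' metadata. Nothing is silently defaulted: missing spacing or origin is an
#' error.
#'
#' Metadata schema (`series.json`): `format` ("xcalqc-series-v1"),
#' `modality`, `value_units`, `spacing_mm` (length 3), `origin_mm` (length
#' 3), optional `acquisition_datetime` and `decay_reference_datetime`
#' (ISO-8601 UTC), optional `rescale_slope`/`rescale_intercept` (defaults 1
#' and 0), and `files`: a list of `{file, z_mm}` entries.
#'
#' @param path Directory containing the series.
#' @return An [image_volume()].
#' @export
read_series <- function(path) {
  meta_path <- file.path(path, "series.json")
  if (!dir.exists(path)) stop("series directory not found: ", path, call. = FALSE)
  if (!file.exists(meta_path)) {
    stop("not a readable series: missing series.json in ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("modality", "value_units", "spacing_mm", "origin_mm", "files")) {
    if (is.null(meta[[key]])) {
      stop("series metadata missing required key: ", key, call. = FALSE)
    }
  }
  spacing <- as.numeric(meta$spacing_mm)
  origin <- as.numeric(meta$origin_mm)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("series metadata has invalid spacing_mm", call. = FALSE)
  }
  files <- meta$files
  if (is.data.frame(files)) files <- split(files, seq_len(nrow(files)))
  entries <- lapply(files, function(f) {
    z <- f$z_mm
    list(file = as.character(f$file),
         z_mm = if (is.null(z) || length(z) == 0L) NA_real_ else as.numeric(z))
  })
  slope <- meta$rescale_slope %||% 1
  intercept <- meta$rescale_intercept %||% 0

  if (length(entries) == 1L && is.na(entries[[1]]$z_mm)) {
    arr <- .read_nii_array(file.path(path, entries[[1]]$file))
    if (length(dim(arr)) != 3L) stop("single-file series must be 3D", call. = FALSE)
  } else {
    z <- vapply(entries, `[[`, numeric(1), "z_mm")
    if (anyNA(z)) stop("slice entries must all carry z_mm", call. = FALSE)
    ord <- order(z)
    entries <- entries[ord]; z <- z[ord]
    if (anyDuplicated(z)) stop("mixed series: duplicate slice positions", call. = FALSE)
    slices <- lapply(entries, function(e) {
      a <- .read_nii_array(file.path(path, e$file))
      d <- dim(a)
      if (length(d) == 3L && d[3] == 1L) { dim(a) <- d[1:2]; d <- dim(a) }
      if (length(d) != 2L) stop("slice files must be 2D", call. = FALSE)
      a
    })
    dims <- vapply(slices, function(s) dim(s), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("mixed series: slice dimensions differ", call. = FALSE)
    }
    if (length(z) > 1L) {
      gaps <- diff(z)
      if (any(abs(gaps - spacing[3]) > 0.01 * spacing[3])) {
        stop("inconsistent slice gaps (beyond 1% of axial spacing)", call. = FALSE)
      }
      # origin refers to the first (lowest-z) slice
      origin[3] <- z[1]
    }
    arr <- array(unlist(slices, use.names = FALSE),
                 dim = unname(c(dims[1, 1], dims[2, 1], length(slices))))
  }

  image_volume(
    values = arr * slope + intercept,
    spacing = spacing, origin = origin,
    modality = meta$modality, value_units = meta$value_units,
    acquisition_datetime =
      if (is.null(meta$acquisition_datetime)) as.POSIXct(NA)
      else parse_datetime_utc(meta$acquisition_datetime),
    decay_reference_datetime =
      if (is.null(meta$decay_reference_datetime)) as.POSIXct(NA)
      else parse_datetime_utc(meta$decay_reference_datetime)
  )
}

.read_nii_array <- function(file) {
  if (!file.exists(file)) stop("series file not found: ", file, call. = FALSE)
  a <- RNifti::readNifti(file)
  array(as.numeric(a), dim = dim(a))
}

#' Convert a PET volume to decay-corrected activity concentration
#'
#' Converts stored activity units to kBq/mL and decay-corrects the values
#' from the volume's decay reference datetime to `at`. With `at` equal to
#' the reference time this is a pure unit conversion.
#'
#' @param vol A PET [image_volume()] in `Bq/mL` or `kBq/mL`.
#' @param spec [decay_spec()] of the imaged nuclide.
#' @param at `POSIXct` target time, default the volume's decay reference.
#' @return An [image_volume()] in kBq/mL.
#' @export
to_concentration <- function(vol, spec, at = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  if (vol$modality != "PET") {
    stop("activity conversion requires a PET volume, got ", vol$modality,
         call. = FALSE)
  }
  if (!vol$value_units %in% c("Bq/mL", "kBq/mL")) {
    stop("volume is not in activity units: ", vol$value_units, call. = FALSE)
  }
  scale <- if (vol$value_units == "Bq/mL") 1e-3 else 1
  out <- vol
  out$values <- vol$values * scale
  out$value_units <- "kBq/mL"
  if (!is.null(at)) {
    if (is.na(vol$decay_reference_datetime)) {
      stop("volume has no decay reference datetime; supply it at read time",
           call. = FALSE)
    }
    fac <- decay_factor(spec, difftime(at, vol$decay_reference_datetime,
                                       units = "secs"))
    out$values <- out$values * fac
    out$decay_reference_datetime <- at
  }
  out
}

#' Create an injection record
#'
#' The decay-corrected injected activity and patient weight used by the SUV
#' normalisation.
#'
#' @param injected_activity Decay-corrected injected activity, MBq.
#' @param assay_datetime `POSIXct` assay time.
#' @param patient_weight Patient weight, kg.
#' @return An `injection_record` object.
#' @export
injection_record <- function(injected_activity, assay_datetime = as.POSIXct(NA),
                             patient_weight) {
  if (!is.numeric(injected_activity) || injected_activity <= 0) {
    stop("invalid record: injected activity must be > 0", call. = FALSE)
  }
  if (!is.numeric(patient_weight) || patient_weight <= 0) {
    stop("invalid record: patient weight must be > 0", call. = FALSE)
  }
  structure(list(injected_activity = injected_activity,
                 assay_datetime = assay_datetime,
                 patient_weight = patient_weight),
            class = "injection_record")
}

#' Convert a concentration volume to body-weight SUV
#'
#' `SUV = A / (I / W)` with A in kBq/mL, I in MBq and W in kg; the units
#' work out to g/mL (`I/W` in MBq/kg equals kBq/g). The caller is
#' responsible for having A and I decay-corrected to a common time; applying
#' the same correction to both cancels out of the ratio. Only the
#' body-weight flavour is implemented.
#'
#' @param vol A PET [image_volume()] in kBq/mL (Bq/mL accepted, converted).
#' @param inj An [injection_record()].
#' @return An [image_volume()] with `value_units = "SUV"` (g/mL).
#' @export
to_suv <- function(vol, inj) {
  stopifnot(inherits(vol, "image_volume"), inherits(inj, "injection_record"))
  if (vol$modality != "PET") stop("SUV requires a PET volume", call. = FALSE)
  if (vol$value_units == "Bq/mL") {
    vol$values <- vol$values * 1e-3
    vol$value_units <- "kBq/mL"
  }
  if (vol$value_units != "kBq/mL") {
    stop("SUV conversion requires an activity-concentration volume", call. = FALSE)
  }
  out <- vol
  # A [kBq/mL] / (I/W [MBq/kg] == [kBq/g]) -> g/mL
  out$values <- vol$values * inj$patient_weight / inj$injected_activity
  out$value_units <- "SUV"
  out
}

# ---- calibration-record tables -------------------------------------------

.record_columns <- c("site_id", "scanner_id", "dose_calibrator_id",
                     "measurement_datetime", "phantom_R", "dose_calibrator_R",
                     "suv_bias", "acf", "phantom_age_days",
                     "roi_mean", "roi_sd", "roi_max", "roi_min",
                     "roi_n_voxels", "roi_u_percent")

.record_schema_version <- "xcalqc-records-v1"

#' Write calibration records to CSV with a JSON sidecar
#'
#' The CSV holds the documented column order (see
#' [calibration_record()]); the JSON sidecar (same path with `.json`
#' appended) records the schema version and datetime convention so the file
#' is re-readable losslessly with [read_records()].
#'
#' @param records A tibble of calibration records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (nrow(records) > 0) {
    missing <- setdiff(.record_columns, names(records))
    if (length(missing)) {
      stop("records missing columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  } else {
    records <- .empty_records()
  }
  out <- records[, .record_columns]
  out$measurement_datetime <- format(out$measurement_datetime,
                                     "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(schema = .record_schema_version, columns = .record_columns,
         datetime_format = "ISO-8601 UTC", n_records = nrow(records)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.empty_records <- function() {
  tibble::tibble(
    site_id = character(), scanner_id = character(),
    dose_calibrator_id = character(),
    measurement_datetime = as.POSIXct(character(), tz = "UTC"),
    phantom_R = numeric(), dose_calibrator_R = numeric(),
    suv_bias = numeric(), acf = numeric(), phantom_age_days = numeric(),
    roi_mean = numeric(), roi_sd = numeric(), roi_max = numeric(),
    roi_min = numeric(), roi_n_voxels = integer(), roi_u_percent = numeric()
  )
}

#' Read calibration records written by [write_records()]
#'
#' The stored SUV bias is recomputed from the stored recovery coefficients
#' on load; any mismatch is a hard error, so a corrupted or hand-edited file
#' cannot silently feed inconsistent biases into reports.
#'
#' @param path CSV path.
#' @return Tibble of calibration records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(site_id = "character",
                                       scanner_id = "character",
                                       dose_calibrator_id = "character"))
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) return(.empty_records())
  df$measurement_datetime <- parse_datetime_utc(df$measurement_datetime)
  recomputed <- df$phantom_R / df$dose_calibrator_R - 1
  bad <- abs(recomputed - df$suv_bias) > 1e-6
  if (any(bad, na.rm = TRUE)) {
    stop("stored suv_bias does not match phantom_R / dose_calibrator_R - 1 ",
         "in row(s) ", paste(which(bad), collapse = ", "), call. = FALSE)
  }
  df
}
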