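#' Analyze one phantom series
#'
#' The full scanner-side chain: read the series (or accept an in-memory
#' volume), convert to kBq/mL, locate the phantom automatically, extract
#' the whole-voxel bounding-box ROI, and divide the ROI mean by the
#' decay-corrected traceable concentration to obtain the recovery
#' coefficient `R = A_measured / A_known`.
#'
#' The comparison time defaults to the volume's decay reference datetime:
#' scanner output is decay-corrected to that instant, so the known value
#' must be decayed to the same instant for the ratio to be meaningful.
#'
#' @param series An [image_volume()] or a series directory for
#'   [read_series()].
#' @param cert [source_certificate()] of the scanner phantom source (must
#'   carry a concentration).
#' @param spec [decay_spec()] of the source nuclide.
#' @param when `POSIXct` comparison time; default the volume's decay
#'   reference datetime, falling back to its acquisition datetime.
#' @param box_mm ROI bounding-box side, mm (default 15).
#' @param ... Further arguments to [locate_active_center()].
#' @return List with `R`, `roi` ([roi_statistics()] result), `center_mm`,
#'   `known_concentration`, `when`.
#' @export
analyze_series <- function(series, cert, spec, when = NULL, box_mm = 15, ...) {
  vol <- if (inherits(series, "image_volume")) series else read_series(series)
  conc <- to_concentration(vol, spec)
  if (is.null(when)) {
    when <- if (!is.na(conc$decay_reference_datetime)) {
      conc$decay_reference_datetime
    } else {
      conc$acquisition_datetime
    }
  }
  if (is.na(when)) {
    stop("no comparison time: the series carries neither a decay reference ",
         "nor an acquisition datetime; pass `when`", call. = FALSE)
  }
  center <- locate_active_center(conc, ...)
  roi <- whole_voxel_roi(conc, center, box_mm = box_mm)
  stats <- roi_statistics(conc, roi)
  known <- known_concentration_at(cert, spec, when)
  list(R = recovery_coefficient(stats$mean, known),
       roi = stats, center_mm = center,
       known_concentration = known, when = when)
}

#' Pair a phantom analysis with a dose-calibrator assay
#'
#' Forms one calibration pair: the dose-calibrator recovery coefficient is
#' the assayed reading over the expected (decayed, response-factor-scaled)
#' reading, and the SUV bias follows as `b = R_P / R_D - 1`. The phantom
#' scan and the assay must fall on the same UTC calendar day (the default
#' pairing window) unless `force = TRUE`.
#'
#' @param phantom Result of [analyze_series()], or a bare phantom recovery
#'   coefficient.
#' @param phantom_datetime `POSIXct` of the phantom measurement (taken from
#'   `phantom$when` when available).
#' @param reading Assayed dose-calibrator reading, MBq (F-18 equivalent).
#' @param assay_datetime `POSIXct` of the assay.
#' @param cert [source_certificate()] of the dose-calibrator source.
#' @param spec [decay_spec()] of the source nuclide.
#' @param response_factor Manufacturer Ge-68 to F-18 response factor (> 0;
#'   no default — it comes from the source datasheet).
#' @param site_id,scanner_id,dose_calibrator_id Identifiers for the record.
#' @param acf Scanner activity calibration factor, if recorded.
#' @param force Pair despite a window violation.
#' @return One-row calibration-record tibble (see [calibration_record()]).
#' @export
pair_measurement <- function(phantom, phantom_datetime = NULL,
                             reading, assay_datetime, cert, spec,
                             response_factor,
                             site_id = "site", scanner_id = NA_character_,
                             dose_calibrator_id = NA_character_,
                             acf = NA_real_, force = FALSE) {
  if (is.list(phantom)) {
    r_p <- phantom$R
    if (is.null(phantom_datetime)) phantom_datetime <- phantom$when
    roi <- phantom$roi
  } else {
    r_p <- phantom
    roi <- NULL
  }
  if (is.null(phantom_datetime)) {
    stop("`phantom_datetime` is required when `phantom` is a bare number",
         call. = FALSE)
  }
  same_day <- format(phantom_datetime, "%Y-%m-%d", tz = "UTC") ==
    format(assay_datetime, "%Y-%m-%d", tz = "UTC")
  if (!same_day && !force) {
    stop("pairing window violation: phantom scan and assay are not on the ",
         "same UTC calendar day (use force = TRUE to override)", call. = FALSE)
  }
  expected <- expected_dose_reading(cert, spec, assay_datetime, response_factor)
  r_d <- recovery_coefficient(reading, expected)
  age <- as.numeric(difftime(phantom_datetime, cert$reference_datetime,
                             units = "days"))
  calibration_record(
    site_id = site_id, scanner_id = scanner_id,
    dose_calibrator_id = dose_calibrator_id,
    measurement_datetime = phantom_datetime,
    phantom_R = r_p, dose_calibrator_R = r_d,
    acf = acf, phantom_age_days = age, roi = roi
  )
}

#' Summary report over calibration records
#'
#' Per-site and overall summaries of the phantom and dose-calibrator
#' recovery coefficients and the SUV bias, plus the ACF-segmented
#' longitudinal report.
#'
#' @param records Calibration-record tibble, or a CSV path written by
#'   [write_records()].
#' @return List with `per_site`, `overall` (summary tibbles for
#'   `phantom_R`, `dose_calibrator_R`, `suv_bias`), and `time_series` (see
#'   [time_series_report()]). Empty input yields empty tables with a
#'   warning.
#' @export
report_records <- function(records) {
  if (is.character(records)) records <- read_records(records)
  if (nrow(records) == 0L) {
    warning("no records: empty report", call. = FALSE)
    return(list(per_site = tibble::tibble(), overall = tibble::tibble(),
                time_series = time_series_report(records)))
  }
  metrics_cols <- c("phantom_R", "dose_calibrator_R", "suv_bias")
  per_site <- dplyr::bind_rows(lapply(metrics_cols, function(cl) {
    s <- summarize_records(records, value = cl, group_by = "site_id")
    s$metric <- cl
    s
  }))
  overall <- dplyr::bind_rows(lapply(metrics_cols, function(cl) {
    s <- summarize_records(records, value = cl, group_by = NULL)
    s$metric <- cl
    s
  }))
  list(per_site = per_site, overall = overall,
       time_series = time_series_report(records))
}

#' Whole-voxel ROI size table
#'
#' Voxel counts produced by the whole-voxel bounding-box rule for a set of
#' box sizes on a given grid, computed by running the actual ROI selection
#' on a dummy volume. On the 2.7 x 2.7 x 3.3 mm grid the 10/15/20-mm boxes
#' give 27, 100 and 294 voxels.
#'
#' @param spacing Voxel spacing, mm.
#' @param boxes Box sides to tabulate, mm.
#' @return Tibble with `box_mm`, `nx`, `ny`, `nz`, `n_voxels`.
#' @export
roi_size_table <- function(spacing = c(2.7, 2.7, 3.3), boxes = c(10, 15, 20)) {
  dims <- pmax(ceiling(max(boxes) / spacing) + 4, 5)
  vol <- image_volume(array(0, dim = dims), spacing = spacing,
                      origin = c(0, 0, 0), modality = "PET",
                      value_units = "kBq/mL")
  center <- vol$origin + (dims - 1) / 2 * spacing
  rows <- lapply(boxes, function(b) {
    roi <- whole_voxel_roi(vol, center, box_mm = b)
    tibble::tibble(box_mm = b, nx = roi$n_axis[1], ny = roi$n_axis[2],
                   nz = roi$n_axis[3], n_voxels = roi$n_voxels)
  })
  dplyr::bind_rows(rows)
}

#' Read and validate a run configuration
#'
#' YAML configuration for command-line runs. Unknown keys are rejected and
#' referenced files must exist, so a typo cannot silently fall back to a
#' default. Recognised keys: `certificate`, `dose_certificate` (paths),
#' `nuclide`, `half_life_days`, `response_factor`, `box_mm`,
#' `threshold_fraction`, `min_component_ml`, `alignment_tolerance_mm`,
#' `pairing_force`, `seed`, `out_dir`, `verbosity`.
#'
#' @param path YAML file.
#' @return Named list of settings merged over defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(
    certificate = NULL, dose_certificate = NULL,
    nuclide = "Ge-68", half_life_days = GE68_HALF_LIFE_DAYS,
    response_factor = NULL, box_mm = 15, threshold_fraction = 0.5,
    min_component_ml = 5, alignment_tolerance_mm = 3,
    pairing_force = FALSE, seed = 1L, out_dir = ".", verbosity = 1L
  )
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, y)
  for (key in c("certificate", "dose_certificate")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config references missing file: ", cfg[[key]], call. = FALSE)
    }
  }
  cfg
}
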