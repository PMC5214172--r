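#' Recovery coefficient
#'
#' The dimensionless ratio of a measured activity (concentration) to the
#' traceable known value: `R = A_measured / A_known`. Used for both the
#' scanner phantom (concentrations, kBq/mL) and the dose calibrator
#' (total activities, MBq).
#'
#' @param measured Measured value.
#' @param known Known (traceable) value, > 0.
#' @return `measured / known`.
#' @export
recovery_coefficient <- function(measured, known) {
  if (!is.numeric(known) || any(known <= 0)) {
    stop("`known` must be > 0", call. = FALSE)
  }
  measured / known
}

#' SUV bias from paired recovery coefficients
#'
#' `b = R_P / R_D - 1`, the net calibration bias that propagates into
#' standardised uptake values when the same dose calibrator assays patient
#' doses and the scanner carries its own calibration: a common scale factor
#' applied to both recovery coefficients cancels.
#'
#' @param r_p Phantom (scanner) recovery coefficient.
#' @param r_d Dose-calibrator recovery coefficient, > 0.
#' @return Dimensionless bias.
#' @export
suv_bias <- function(r_p, r_d) {
  if (!is.numeric(r_d) || any(r_d <= 0)) {
    stop("`r_d` must be > 0", call. = FALSE)
  }
  r_p / r_d - 1
}

#' Coefficient of variation across repeated measurements
#'
#' `100 * sd / mean`, with the sample SD (divide by n - 1): values here are
#' repeated measurements whose spread estimates an underlying variability.
#' (Contrast the intra-ROI `u` of [roi_statistics()], which uses the
#' population SD because it describes a fixed voxel set.)
#'
#' @param values Numeric vector, length >= 2, positive mean.
#' @return COV in percent.
#' @export
cov_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("COV needs at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("COV undefined for non-positive mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' COV of a printed mean +/- SD pair
#'
#' Convenience for comparing against reported `mean +/- sd (COV = x%)`
#' figures: `100 * sd / mean` rounded half away from zero at `digits`
#' decimals.
#'
#' @param mean Reported mean.
#' @param sd Reported SD.
#' @param digits Decimals of the printed COV (default 1).
#' @return COV in percent at the printed precision.
#' @export
cov_from_mean_sd <- function(mean, sd, digits = 1) {
  if (mean <= 0) stop("COV undefined for non-positive mean", call. = FALSE)
  round_half_away(100 * sd / mean, digits)
}

#' Assemble one calibration record
#'
#' One paired phantom + dose-calibrator measurement. The SUV bias is always
#' computed from the two recovery coefficients, never supplied, so a record
#' can never carry an inconsistent `b`.
#'
#' @param site_id,scanner_id,dose_calibrator_id Identifiers.
#' @param measurement_datetime `POSIXct` of the calibration pair.
#' @param phantom_R Scanner phantom recovery coefficient, > 0.
#' @param dose_calibrator_R Dose-calibrator recovery coefficient, > 0.
#' @param acf Scanner activity calibration factor at scan time (opaque
#'   scanner-defined scale, recorded for segmentation), or `NA`.
#' @param phantom_age_days Phantom age at measurement, days, or `NA`.
#' @param roi Optional [roi_statistics()] result; its summary fields are
#'   flattened into the record.
#' @return One-row tibble in the documented column order.
#' @export
calibration_record <- function(site_id, scanner_id = NA_character_,
                               dose_calibrator_id = NA_character_,
                               measurement_datetime,
                               phantom_R, dose_calibrator_R,
                               acf = NA_real_, phantom_age_days = NA_real_,
                               roi = NULL) {
  if (!is.numeric(phantom_R) || phantom_R <= 0) {
    stop("`phantom_R` must be > 0", call. = FALSE)
  }
  if (!is.numeric(dose_calibrator_R) || dose_calibrator_R <= 0) {
    stop("`dose_calibrator_R` must be > 0", call. = FALSE)
  }
  tibble::tibble(
    site_id = as.character(site_id),
    scanner_id = as.character(scanner_id),
    dose_calibrator_id = as.character(dose_calibrator_id),
    measurement_datetime = measurement_datetime,
    phantom_R = phantom_R,
    dose_calibrator_R = dose_calibrator_R,
    suv_bias = suv_bias(phantom_R, dose_calibrator_R),
    acf = acf,
    phantom_age_days = phantom_age_days,
    roi_mean = if (is.null(roi)) NA_real_ else roi$mean,
    roi_sd = if (is.null(roi)) NA_real_ else roi$sd,
    roi_max = if (is.null(roi)) NA_real_ else roi$max,
    roi_min = if (is.null(roi)) NA_real_ else roi$min,
    roi_n_voxels = if (is.null(roi)) NA_integer_ else as.integer(roi$n_voxels),
    roi_u_percent = if (is.null(roi)) NA_real_ else roi$u
  )
}

#' Grouped summary statistics
#'
#' Per-group n, mean, SD, COV (percent), min and max of one numeric column,
#' with deterministic lexicographic group ordering. SD and COV are reported
#' only for groups with at least two values.
#'
#' @param records Tibble (e.g. calibration records).
#' @param value Name of the numeric column to summarise (default
#'   `"phantom_R"`).
#' @param group_by Name of the grouping column, or `NULL` for a single
#'   overall group.
#' @return Tibble with columns `group`, `n`, `mean`, `sd`, `cov_percent`,
#'   `min`, `max`.
#' @export
summarize_records <- function(records, value = "phantom_R", group_by = NULL) {
  if (!value %in% names(records)) {
    stop("unknown value column: ", value, call. = FALSE)
  }
  if (!is.null(group_by) && !group_by %in% names(records)) {
    stop("unknown group key: ", group_by, call. = FALSE)
  }
  g <- if (is.null(group_by)) rep("all", nrow(records)) else
    as.character(records[[group_by]])
  v <- records[[value]]
  out <- lapply(sort(unique(g)), function(grp) {
    x <- v[g == grp]
    tibble::tibble(
      group = grp, n = length(x), mean = mean(x),
      sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
      cov_percent = if (length(x) >= 2 && mean(x) > 0)
        100 * stats::sd(x) / mean(x) else NA_real_,
      min = min(x), max = max(x)
    )
  })
  dplyr::bind_rows(out)
}

#' Longitudinal report with calibration-period segmentation
#'
#' Orders records in time within each site and splits them into calibration
#' segments wherever the scanner's activity calibration factor (ACF)
#' changes: the scanner applies the ACF as a global scale, so a
#' recalibration step shifts every subsequent R. Within-segment statistics
#' separate drift inside a calibration period from the jumps between them.
#' Any relative ACF change above `acf_rel_tol` starts a new segment; the
#' default treats any change as a recalibration. Records with missing ACF
#' continue the current segment.
#'
#' @param records Calibration-record tibble.
#' @param acf_rel_tol Relative ACF change that opens a new segment.
#' @return List with `records` (input plus `segment` column, ordered by
#'   site and time), `segments` (per site x segment summary of `phantom_R`),
#'   and `overall` (per-site summary across segments). Duplicate
#'   (site, datetime) pairs are kept with a warning.
#' @export
time_series_report <- function(records, acf_rel_tol = 1e-6) {
  if (nrow(records) == 0L) {
    return(list(records = records, segments = tibble::tibble(),
                overall = tibble::tibble()))
  }
  records <- records[order(records$site_id, records$measurement_datetime), ]
  key <- paste(records$site_id, format(records$measurement_datetime))
  if (anyDuplicated(key)) {
    warning("duplicate (site, datetime) pairs present; keeping all",
            call. = FALSE)
  }
  seg <- integer(nrow(records))
  for (site in unique(records$site_id)) {
    rows <- which(records$site_id == site)
    s <- 1L
    last_acf <- NA_real_
    for (r in rows) {
      acf <- records$acf[r]
      if (!is.na(acf) && !is.na(last_acf) &&
          abs(acf - last_acf) > acf_rel_tol * abs(last_acf)) {
        s <- s + 1L
      }
      seg[r] <- s
      if (!is.na(acf)) last_acf <- acf
    }
  }
  records$segment <- seg
  records$site_segment <- paste0(records$site_id, "/", seg)
  segments <- summarize_records(records, value = "phantom_R",
                                group_by = "site_segment")
  overall <- summarize_records(records, value = "phantom_R",
                               group_by = "site_id")
  records$site_segment <- NULL
  list(records = records, segments = segments, overall = overall)
}
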