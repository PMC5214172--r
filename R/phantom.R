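#' Half-life constants
#'
#' Reference half-lives for the nuclides encountered in sealed-source
#' cross-calibration work. The parent Ge-68 half-life governs a sealed
#' Ge-68/Ga-68 source in secular equilibrium; F-18 is needed when clinical
#' injections are decay-corrected.
#'
#' @format Numeric scalars: `GE68_HALF_LIFE_DAYS` (days) and
#'   `F18_HALF_LIFE_MINUTES` (minutes).
#' @name half_lives
NULL

#' @rdname half_lives
#' @export
GE68_HALF_LIFE_DAYS <- 270.95

#' @rdname half_lives
#' @export
F18_HALF_LIFE_MINUTES <- 109.77

.seconds_per_unit <- c(seconds = 1, minutes = 60, hours = 3600, days = 86400)

#' Create a decay specification
#'
#' A nuclide name together with its half-life. The half-life unit is carried
#' explicitly so that sources with day-scale half-lives (Ge-68) and
#' minute-scale ones (F-18) are handled by the same machinery.
#'
#' @param nuclide Character name, e.g. `"Ge-68"`.
#' @param half_life Positive half-life in `unit`.
#' @param unit One of `"seconds"`, `"minutes"`, `"hours"`, `"days"`.
#' @return A `decay_spec` object.
#' @examples
#' ge68 <- decay_spec("Ge-68", 270.95, "days")
#' decay_factor(ge68, as.difftime(270.95, units = "days"))
#' @export
decay_spec <- function(nuclide, half_life, unit = c("days", "minutes", "hours", "seconds")) {
  unit <- match.arg(unit)
  if (!is.numeric(half_life) || length(half_life) != 1L || !is.finite(half_life) ||
      half_life <= 0) {
    stop("`half_life` must be a single positive number", call. = FALSE)
  }
  structure(
    list(nuclide = as.character(nuclide), half_life = half_life, unit = unit,
         half_life_seconds = half_life * .seconds_per_unit[[unit]]),
    class = "decay_spec"
  )
}

#' @export
print.decay_spec <- function(x, ...) {
  cat(sprintf("<decay_spec> %s: half-life %g %s\n", x$nuclide, x$half_life, x$unit))
  invisible(x)
}

#' Radioactive decay factor over an elapsed interval
#'
#' Returns `2^(-elapsed / half_life)`. Negative elapsed times back-correct
#' (the factor exceeds 1), which is what a calibration needs when the
#' reference datetime lies in the future of the measurement.
#'
#' @param spec A [decay_spec()].
#' @param elapsed Either a [difftime] or a number interpreted in the unit of
#'   `spec`.
#' @return Dimensionless fraction of activity remaining.
#' @export
decay_factor <- function(spec, elapsed) {
  stopifnot(inherits(spec, "decay_spec"))
  secs <- .elapsed_seconds(elapsed, spec$unit)
  2^(-secs / spec$half_life_seconds)
}

.elapsed_seconds <- function(elapsed, default_unit) {
  if (inherits(elapsed, "difftime")) {
    as.numeric(elapsed, units = "secs")
  } else if (is.numeric(elapsed)) {
    elapsed * .seconds_per_unit[[default_unit]]
  } else {
    stop("`elapsed` must be a difftime or a number", call. = FALSE)
  }
}

#' Create a source certificate
#'
#' The traceable datasheet of one sealed source: its activity (and, for
#' scanner phantom sources, activity concentration) at a stated reference
#' datetime, with the certificate's stated uncertainty. Scanner sources carry
#' a concentration because PET measures kBq/mL; dose-calibrator sources carry
#' activity only.
#'
#' @param source_id Identifier printed on the source.
#' @param nuclide Nuclide name, e.g. `"Ge-68"`.
#' @param reference_datetime `POSIXct` timestamp the stated values refer to.
#'   Timezone-aware; use UTC unless you have a reason not to.
#' @param reference_activity Activity in MBq at `reference_datetime`.
#' @param reference_concentration Activity concentration in kBq/mL at
#'   `reference_datetime`, or `NA` for dose-calibrator-style sources.
#' @param stated_uncertainty Fractional uncertainty of the certificate,
#'   e.g. 0.025 for +/-2.5 percent at 95 percent confidence.
#' @param active_diameter,active_height Active-region dimensions in mm
#'   (optional, scanner sources).
#' @return A `source_certificate` object.
#' @examples
#' cert <- source_certificate(
#'   "XC-001", "Ge-68",
#'   reference_datetime = as.POSIXct("2013-03-03 00:00:00", tz = "UTC"),
#'   reference_activity = 20, reference_concentration = 250,
#'   stated_uncertainty = 0.025
#' )
#' @export
source_certificate <- function(source_id, nuclide, reference_datetime,
                               reference_activity,
                               reference_concentration = NA_real_,
                               stated_uncertainty = 0.025,
                               active_diameter = NA_real_,
                               active_height = NA_real_) {
  if (!inherits(reference_datetime, "POSIXct")) {
    stop("`reference_datetime` must be POSIXct (timezone-aware)", call. = FALSE)
  }
  if (!is.numeric(reference_activity) || reference_activity <= 0) {
    stop("`reference_activity` must be > 0", call. = FALSE)
  }
  if (!is.na(reference_concentration) && reference_concentration <= 0) {
    stop("`reference_concentration` must be > 0 where present", call. = FALSE)
  }
  if (!is.numeric(stated_uncertainty) || stated_uncertainty <= 0 ||
      stated_uncertainty >= 1) {
    stop("`stated_uncertainty` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(source_id = as.character(source_id), nuclide = as.character(nuclide),
         reference_datetime = reference_datetime,
         reference_activity = reference_activity,
         reference_concentration = reference_concentration,
         stated_uncertainty = stated_uncertainty,
         active_diameter = active_diameter, active_height = active_height),
    class = "source_certificate"
  )
}

#' @export
print.source_certificate <- function(x, ...) {
  cat(sprintf("<source_certificate> %s (%s)\n", x$source_id, x$nuclide))
  cat(sprintf("  reference: %s\n", format(x$reference_datetime, usetz = TRUE)))
  cat(sprintf("  activity: %g MBq", x$reference_activity))
  if (!is.na(x$reference_concentration)) {
    cat(sprintf(", concentration: %g kBq/mL", x$reference_concentration))
  }
  cat(sprintf("\n  stated uncertainty: +/-%g%%\n", 100 * x$stated_uncertainty))
  invisible(x)
}

#' Read a source certificate from a YAML file
#'
#' Schema (keys): `source_id`, `nuclide`, `reference_datetime` (ISO-8601,
#' assumed UTC when no offset given), `reference_activity_mbq`,
#' `reference_concentration_kbq_ml` (optional), `stated_uncertainty`
#' (optional, default 0.025), `active_diameter_mm`, `active_height_mm`
#' (optional).
#'
#' @param path Path to the YAML certificate file.
#' @return A [source_certificate()].
#' @export
read_certificate <- function(path) {
  if (!file.exists(path)) stop("certificate file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  required <- c("source_id", "nuclide", "reference_datetime", "reference_activity_mbq")
  missing <- setdiff(required, names(y))
  if (length(missing)) {
    stop("certificate missing keys: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  source_certificate(
    source_id = y$source_id, nuclide = y$nuclide,
    reference_datetime = parse_datetime_utc(y$reference_datetime),
    reference_activity = y$reference_activity_mbq,
    reference_concentration = y$reference_concentration_kbq_ml %||% NA_real_,
    stated_uncertainty = y$stated_uncertainty %||% 0.025,
    active_diameter = y$active_diameter_mm %||% NA_real_,
    active_height = y$active_height_mm %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an ISO-8601 datetime as UTC
#'
#' Accepts `"YYYY-MM-DD"`, `"YYYY-MM-DD HH:MM:SS"` and the `T`-separated
#' form, with an optional trailing `Z`.
#'
#' @param x Character scalar.
#' @return `POSIXct` in UTC.
#' @export
parse_datetime_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- sub("Z$", "", as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (any(is.na(out))) stop("cannot parse datetime: ", x, call. = FALSE)
  out
}

#' Decay-corrected known concentration of a phantom source
#'
#' The traceable concentration the scanner should read at time `when`:
#' the certificate concentration decayed from the certificate's reference
#' datetime. This is the denominator of the phantom recovery coefficient.
#'
#' @param cert A [source_certificate()] with a `reference_concentration`.
#' @param spec The matching [decay_spec()].
#' @param when `POSIXct` measurement time.
#' @return Concentration in kBq/mL.
#' @export
known_concentration_at <- function(cert, spec, when) {
  stopifnot(inherits(cert, "source_certificate"))
  if (is.na(cert$reference_concentration)) {
    stop("certificate has no reference concentration: this looks like a ",
         "dose-calibrator source, not a scanner phantom source", call. = FALSE)
  }
  if (!inherits(when, "POSIXct")) stop("`when` must be POSIXct", call. = FALSE)
  cert$reference_concentration *
    decay_factor(spec, difftime(when, cert$reference_datetime, units = "secs"))
}

#' Expected dose-calibrator reading of a sealed standard
#'
#' The decayed certificate activity multiplied by the relative response
#' factor that converts the stated Ge-68 activity to the F-18-equivalent
#' activity a dose calibrator on its FDG setting would display. The factor is
#' supplied by the source manufacturer; there is no universal default, so it
#' is a required argument. The result is the denominator of the
#' dose-calibrator recovery coefficient.
#'
#' @param cert A [source_certificate()].
#' @param spec The matching [decay_spec()].
#' @param when `POSIXct` assay time.
#' @param response_factor Positive dimensionless manufacturer response factor.
#' @return Expected reading in MBq (F-18 equivalent).
#' @export
expected_dose_reading <- function(cert, spec, when, response_factor) {
  stopifnot(inherits(cert, "source_certificate"))
  if (!is.numeric(response_factor) || response_factor <= 0) {
    stop("`response_factor` must be > 0 (supplied on the source datasheet)",
         call. = FALSE)
  }
  if (!inherits(when, "POSIXct")) stop("`when` must be POSIXct", call. = FALSE)
  cert$reference_activity *
    decay_factor(spec, difftime(when, cert$reference_datetime, units = "secs")) *
    response_factor
}

#' Density from weighing in air and under water
#'
#' Archimedes: the mass deficit under water equals the displaced water mass,
#' so `density = mass_air * water_density / (mass_air - mass_water)`. Used to
#' track the cured-epoxy density of the sealed sources over time.
#'
#' @param mass_air Mass weighed in air, g.
#' @param mass_water Apparent mass weighed under water, g.
#' @param water_density Density of the water bath, g/mL (default 1.0).
#' @return Density in g/mL.
#' @export
density_from_weighing <- function(mass_air, mass_water, water_density = 1.0) {
  if (!is.numeric(mass_air) || !is.numeric(mass_water) || mass_air <= 0) {
    stop("masses must be positive numbers", call. = FALSE)
  }
  if (mass_air <= mass_water) {
    stop("invalid measurement: mass in air must exceed apparent mass in water",
         call. = FALSE)
  }
  mass_air * water_density / (mass_air - mass_water)
}

#' Percent change between two values
#'
#' @param old Reference value (non-zero).
#' @param new New value.
#' @return `100 * (new - old) / old`.
#' @export
percent_change <- function(old, new) {
  if (!is.numeric(old) || any(old == 0)) {
    stop("undefined change: `old` must be non-zero", call. = FALSE)
  }
  100 * (new - old) / old
}

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals (0.125 -> 0.13 at two
#' decimals, -0.125 -> -0.13), as used when comparing computed percentages
#' with values printed at fixed precision. Base `round()` rounds half to
#' even, which differs on exact midpoints.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
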