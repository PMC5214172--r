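# Shared fixtures: a nominal Ge-68 phantom certificate, its decay spec, and
# small helper constructors used across the module tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_time <- as.POSIXct("2013-03-03 00:00:00", tz = "UTC")

ge68 <- decay_spec("Ge-68", GE68_HALF_LIFE_DAYS, "days")

phantom_cert <- source_certificate(
  "TEST-P01", "Ge-68", reference_datetime = ref_time,
  reference_activity = 20, reference_concentration = 250,
  stated_uncertainty = 0.025, active_diameter = 45, active_height = 45
)

dose_cert <- source_certificate(
  "TEST-D01", "Ge-68", reference_datetime = ref_time,
  reference_activity = 0.90, stated_uncertainty = 0.025
)

# A uniform PET volume with explicit geometry.
uniform_volume <- function(value, dims = c(8, 8, 4),
                           spacing = c(2.7, 2.7, 3.3),
                           units = "kBq/mL") {
  image_volume(array(value, dim = dims), spacing = spacing,
               origin = c(0, 0, 0), modality = "PET", value_units = units,
               decay_reference_datetime = ref_time)
}

# Render the default noiseless scene once per test file run.
default_render <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      v <- render_scene(phantom_scene())
      v$pet$decay_reference_datetime <- ref_time
      cache <<- v
    }
    cache
  }
})

# Independent oracle for the whole-voxel rule along one axis: the largest
# contiguous run of whole voxels whose physical extent n * spacing fits
# inside the box, found by enumeration rather than arithmetic.
max_whole_voxels <- function(box_mm, spacing_mm, n_max = 1000) {
  best <- 0L
  for (n in seq_len(n_max)) {
    if (n * spacing_mm <= box_mm + 1e-9) best <- n else break
  }
  best
}

# Brute-force single-pass summary used as the oracle for summarize_records().
brute_summary <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- if (n >= 2) sqrt(sum((x - m)^2) / (n - 1)) else NA_real_
  list(n = n, mean = m, sd = s,
       cov = if (n >= 2 && m > 0) 100 * s / m else NA_real_,
       min = min(x), max = max(x))
}

# A synthetic multisite record table: n records spread over sites.
make_records <- function(n = 24, n_sites = 6, seed = 42) {
  withr::with_seed(seed, {
    sites <- sprintf("site%02d", rep_len(seq_len(n_sites), n))
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      calibration_record(
        site_id = sites[i], scanner_id = paste0("scanner-", sites[i]),
        dose_calibrator_id = paste0("dc-", sites[i]),
        measurement_datetime = ref_time + i * 30 * 86400,
        phantom_R = stats::rnorm(1, 0.944, 0.038),
        dose_calibrator_R = stats::rnorm(1, 0.964, 0.033),
        acf = 1.0, phantom_age_days = i * 30
      )
    }))
  })
}
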