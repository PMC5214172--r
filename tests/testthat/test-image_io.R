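test_that("image_volume refuses silently defaulted geometry and bad units", {
  a <- array(1, dim = c(4, 4, 2))
  expect_error(image_volume(a, origin = c(0, 0, 0), modality = "PET",
                            value_units = "kBq/mL"), "spacing")
  expect_error(image_volume(a, spacing = c(2.7, 2.7, 3.3), modality = "PET",
                            value_units = "kBq/mL"), "origin")
  expect_error(image_volume(a, spacing = c(2.7, -1, 3.3), origin = c(0, 0, 0),
                            modality = "PET", value_units = "kBq/mL"),
               "positive")
  expect_error(image_volume(a, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            modality = "CT", value_units = "kBq/mL"), "HU")
  expect_error(image_volume(a, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            modality = "PET", value_units = "HU"), "CT")
})

test_that("a rendered series round-trips values, geometry and timestamps", {
  vols <- default_render()
  for (fmt in c("nifti-3d", "nifti-slices")) {
    dir <- withr::local_tempdir()
    render_series(vols$pet, dir, format = fmt, seed = 123L)
    back <- read_series(dir)
    expect_equal(back$spacing, c(2.7, 2.7, 3.3))
    expect_equal(back$origin, vols$pet$origin)
    expect_equal(back$modality, "PET")
    expect_equal(back$value_units, "kBq/mL")
    expect_equal(back$decay_reference_datetime,
                 vols$pet$decay_reference_datetime)
    # write precision well within 0.1% of the plateau value
    expect_lt(max(abs(back$values - vols$pet$values)), 0.001 * 250)
  }
})

test_that("slice order in the metadata does not affect the volume", {
  vols <- default_render()
  dir <- withr::local_tempdir()
  render_series(vols$pet, dir, format = "nifti-slices")
  sorted <- read_series(dir)
  meta_path <- file.path(dir, "series.json")
  meta <- jsonlite::read_json(meta_path)
  meta$files <- withr::with_seed(5, sample(meta$files))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  shuffled <- read_series(dir)
  expect_identical(shuffled$values, sorted$values)
  expect_identical(shuffled$origin, sorted$origin)
})

test_that("read_series rejects broken series", {
  vols <- default_render()
  dir <- withr::local_tempdir()
  expect_error(read_series(file.path(dir, "nope")), "not found")
  render_series(vols$pet, dir, format = "nifti-slices")
  meta_path <- file.path(dir, "series.json")
  meta <- jsonlite::read_json(meta_path)

  # inconsistent slice gap beyond 1% of axial spacing
  broken <- meta
  broken$files[[3]]$z_mm <- broken$files[[3]]$z_mm + 0.5
  jsonlite::write_json(broken, meta_path, auto_unbox = TRUE)
  expect_error(read_series(dir), "slice gaps")

  # duplicate slice position counts as a mixed series
  broken <- meta
  broken$files[[2]]$z_mm <- broken$files[[1]]$z_mm
  jsonlite::write_json(broken, meta_path, auto_unbox = TRUE)
  expect_error(read_series(dir), "mixed series")

  # missing spacing is an error, never a default
  broken <- meta
  broken$spacing_mm <- NULL
  jsonlite::write_json(broken, meta_path, auto_unbox = TRUE)
  expect_error(read_series(dir), "spacing")
})

test_that("rescale slope and intercept are applied on read", {
  vols <- default_render()
  dir <- withr::local_tempdir()
  render_series(vols$pet, dir, format = "nifti-3d")
  meta_path <- file.path(dir, "series.json")
  meta <- jsonlite::read_json(meta_path)
  meta$rescale_slope <- 2
  meta$rescale_intercept <- 10
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  scaled <- read_series(dir)
  expect_equal(scaled$values, vols$pet$values * 2 + 10, tolerance = 1e-5)
})

test_that("to_concentration converts units and decay-corrects", {
  vol <- uniform_volume(250000, units = "Bq/mL")
  conc <- to_concentration(vol, ge68)
  expect_equal(conc$value_units, "kBq/mL")
  expect_equal(unique(as.numeric(conc$values)), 250)

  # pure unit conversion at the reference time
  same <- to_concentration(uniform_volume(250), ge68, at = ref_time)
  expect_equal(unique(as.numeric(same$values)), 250)

  # one half-life later the values halve
  later <- to_concentration(uniform_volume(250), ge68,
                            at = ref_time + GE68_HALF_LIFE_DAYS * 86400)
  expect_equal(unique(as.numeric(later$values)), 125)

  ct <- image_volume(array(0, dim = c(4, 4, 2)), spacing = c(1, 1, 1),
                     origin = c(0, 0, 0), modality = "CT", value_units = "HU")
  expect_error(to_concentration(ct, ge68), "PET")
})

test_that("SUV of a uniform distribution is 1 g/mL regardless of dose and size", {
  # body volume V mL at density 1 g/mL weighs V g
  for (case in list(c(I = 100, V = 50000), c(I = 370, V = 70000))) {
    a_kbq_ml <- case[["I"]] * 1000 / case[["V"]]  # uniformly distributed
    vol <- uniform_volume(a_kbq_ml)
    inj <- injection_record(case[["I"]], patient_weight = case[["V"]] / 1000)
    suv <- to_suv(vol, inj)
    expect_equal(suv$value_units, "SUV")
    expect_equal(unique(as.numeric(suv$values)), 1.0)
  }
})

test_that("SUV arithmetic is linear in activity and inverse in dose", {
  vol <- uniform_volume(2)
  inj <- injection_record(100, patient_weight = 50)
  expect_equal(unique(as.numeric(to_suv(vol, inj)$values)), 1.0)
  # doubling the injected activity halves SUV
  inj2 <- injection_record(200, patient_weight = 50)
  expect_equal(unique(as.numeric(to_suv(vol, inj2)$values)), 0.5)
  # Bq/mL input is converted before normalising
  volb <- uniform_volume(2000, units = "Bq/mL")
  expect_equal(unique(as.numeric(to_suv(volb, inj)$values)), 1.0)
  expect_error(injection_record(-1, patient_weight = 50), "> 0")
  expect_error(injection_record(100, patient_weight = 0), "> 0")
})

test_that("decay correction applied consistently to A and I cancels in SUV", {
  vol <- uniform_volume(2)
  inj <- injection_record(100, patient_weight = 50)
  base <- to_suv(vol, inj)
  fac <- decay_factor(ge68, 123)
  vol2 <- vol; vol2$values <- vol$values * fac
  inj2 <- injection_record(100 * fac, patient_weight = 50)
  expect_equal(to_suv(vol2, inj2)$values, base$values, tolerance = 1e-12)
})

test_that("calibration records round-trip through CSV + JSON sidecar", {
  recs <- make_records(n = 5, n_sites = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_records(path)
  expect_equal(nrow(back), 5)
  expect_equal(back$phantom_R, recs$phantom_R, tolerance = 1e-12)
  expect_equal(back$suv_bias, recs$suv_bias, tolerance = 1e-12)
  expect_equal(back$measurement_datetime, recs$measurement_datetime)
  expect_equal(back$site_id, recs$site_id)

  # header-only file for an empty record set
  empty_path <- withr::local_tempfile(fileext = ".csv")
  write_records(recs[0, ], empty_path)
  expect_equal(nrow(read_records(empty_path)), 0)
  expect_equal(length(readLines(empty_path)), 1L)
})

test_that("a tampered suv_bias column is rejected on load", {
  recs <- make_records(n = 3, n_sites = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, path)
  df <- utils::read.csv(path)
  df$suv_bias[2] <- df$suv_bias[2] + 0.01
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_records(path), "does not match")
})
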