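#' Describe a synthetic phantom scene
#'
#' Ground-truth geometry and activity for the simulator: a sealed 45-mm
#' cylindrical active region (nominally 250 kBq/mL) mounted inside a 20-cm
#' water-filled flood cylinder, on a regular voxel grid. The grid is centred
#' on the flood-phantom axis at (0, 0, 0) mm; the axial (z) axis is the
#' cylinder axis. By default the active region is mounted 70 mm below the
#' flood axis, mimicking a bracket mount at the bottom of the flood phantom.
#'
#' The two bundled grids correspond to common whole-body reconstructions:
#' `voxel = "batch1"` gives 5.5 x 5.5 x 3.3 mm voxels, `"batch2"` (default)
#' 2.7 x 2.7 x 3.3 mm.
#'
#' @param active_diameter,active_height Active-region size, mm.
#' @param active_concentration Activity concentration of the active region,
#'   kBq/mL.
#' @param flood_diameter,flood_height Flood-phantom cylinder size, mm.
#' @param background_medium `"water"`, `"air"`, or `"activity"` (water
#'   spiked to `background_fraction` of the active concentration).
#' @param background_fraction Fraction of the active concentration present
#'   in the flood water when `background_medium = "activity"`.
#' @param phantom_center_mm Centre of the active region, mm.
#' @param rotation_deg Rotation of the mount about the flood-phantom axis,
#'   degrees (see [misposition()]).
#' @param voxel `"batch1"`, `"batch2"`, or `NULL` to give spacing/shape
#'   explicitly.
#' @param voxel_spacing,grid_shape Explicit grid when `voxel` is `NULL`.
#' @return A `phantom_scene` object.
#' @export
phantom_scene <- function(active_diameter = 45, active_height = 45,
                          active_concentration = 250,
                          flood_diameter = 200, flood_height = 150,
                          background_medium = c("water", "air", "activity"),
                          background_fraction = 0.15,
                          phantom_center_mm = c(0, -70, 0),
                          rotation_deg = 0,
                          voxel = "batch2",
                          voxel_spacing = NULL, grid_shape = NULL) {
  background_medium <- match.arg(background_medium)
  if (!is.null(voxel)) {
    voxel <- match.arg(voxel, c("batch1", "batch2"))
    voxel_spacing <- if (voxel == "batch1") c(5.5, 5.5, 3.3) else c(2.7, 2.7, 3.3)
    grid_shape <- if (voxel == "batch1") c(42L, 42L, 46L) else c(84L, 84L, 46L)
  }
  if (is.null(voxel_spacing) || is.null(grid_shape)) {
    stop("give either `voxel` or both `voxel_spacing` and `grid_shape`",
         call. = FALSE)
  }
  if (any(c(active_diameter, active_height, flood_diameter, flood_height) <= 0)) {
    stop("diameters and heights must be positive", call. = FALSE)
  }
  if (background_fraction < 0) stop("background_fraction must be >= 0", call. = FALSE)
  scene <- structure(
    list(active_diameter = active_diameter, active_height = active_height,
         active_concentration = active_concentration,
         flood_diameter = flood_diameter, flood_height = flood_height,
         background_medium = background_medium,
         background_fraction = background_fraction,
         phantom_center_mm = as.numeric(phantom_center_mm),
         rotation_deg = rotation_deg,
         voxel_spacing = as.numeric(voxel_spacing),
         grid_shape = as.integer(grid_shape)),
    class = "phantom_scene"
  )
  .check_scene_geometry(scene)
  scene
}

.check_scene_geometry <- function(scene) {
  c_xy <- scene$phantom_center_mm[1:2]
  if (sqrt(sum(c_xy^2)) + scene$active_diameter / 2 > scene$flood_diameter / 2 + 1e-9) {
    stop("geometry error: active cylinder extends outside the flood phantom ",
         "transaxially", call. = FALSE)
  }
  if (abs(scene$phantom_center_mm[3]) + scene$active_height / 2 >
      scene$flood_height / 2 + 1e-9) {
    stop("geometry error: active cylinder extends outside the flood phantom ",
         "axially", call. = FALSE)
  }
  ext <- scene$voxel_spacing * scene$grid_shape / 2
  if (any(abs(scene$phantom_center_mm) + c(rep(scene$active_diameter / 2, 2),
                                           scene$active_height / 2) > ext)) {
    stop("out of grid: active cylinder extends outside the voxel grid",
         call. = FALSE)
  }
  invisible(scene)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_scene> active %g mm dia x %g mm @ %g kBq/mL at (%g, %g, %g) mm\n",
    "  flood %g mm dia, background %s; grid %d x %d x %d @ %g x %g x %g mm\n"),
    x$active_diameter, x$active_height, x$active_concentration,
    x$phantom_center_mm[1], x$phantom_center_mm[2], x$phantom_center_mm[3],
    x$flood_diameter, x$background_medium,
    x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
    x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  invisible(x)
}

#' Point-spread-function specification
#'
#' Gaussian smoothing widths emulating the reconstruction filter: default
#' 8 mm FWHM in the two transaxial dimensions and 4.6 mm axially.
#'
#' @param fwhm_transaxial,fwhm_axial FWHM in mm, >= 0 (0 disables).
#' @return A `psf_spec` object.
#' @export
psf_spec <- function(fwhm_transaxial = 8, fwhm_axial = 4.6) {
  if (fwhm_transaxial < 0 || fwhm_axial < 0) stop("FWHMs must be >= 0", call. = FALSE)
  structure(list(fwhm_transaxial = fwhm_transaxial, fwhm_axial = fwhm_axial),
            class = "psf_spec")
}

#' Noise specification
#'
#' Voxel noise for rendered volumes. `"gaussian"` adds i.i.d. noise with
#' SD equal to `magnitude` times the plateau (robust maximum) value;
#' `"scaled-poisson"` draws Poisson counts with `magnitude` expected counts
#' at the plateau and rescales back, so the mean is preserved in
#' expectation. The seed is mandatory for any stochastic model and is
#' recorded in rendered-series metadata.
#'
#' @param model `"none"`, `"gaussian"`, or `"scaled-poisson"`.
#' @param magnitude Noise magnitude (fraction of plateau, or plateau counts).
#' @param seed Integer RNG seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(model = c("none", "gaussian", "scaled-poisson"),
                       magnitude = 0.005, seed = NA_integer_) {
  model <- match.arg(model)
  if (magnitude < 0) stop("noise magnitude must be >= 0", call. = FALSE)
  if (model != "none" && magnitude > 0 && is.na(seed)) {
    stop("a seed is required for stochastic noise", call. = FALSE)
  }
  structure(list(model = model, magnitude = magnitude, seed = seed),
            class = "noise_spec")
}

#' Render the ground-truth volumes of a scene
#'
#' Paints the scene onto its voxel grid: voxels inside the active cylinder
#' get the active concentration, flood voxels the background concentration,
#' voxels outside the flood get zero. Boundary voxels receive analytic
#' partial-volume fractions from 2 x 2 x 2 subsampling (ROIs stay well away
#' from edges, so finer subdivision buys nothing). A companion CT-like
#' volume assigns nominal HU to the epoxy insert (+150), water (0) and air
#' (-1000).
#'
#' @param scene A [phantom_scene()].
#' @param acquisition_datetime,decay_reference_datetime Timestamps stamped
#'   on the PET volume.
#' @return List with `pet` (kBq/mL [image_volume()]) and `ct` (HU
#'   [image_volume()]).
#' @export
build_scene <- function(scene,
                        acquisition_datetime = as.POSIXct(NA),
                        decay_reference_datetime = as.POSIXct(NA)) {
  stopifnot(inherits(scene, "phantom_scene"))
  .check_scene_geometry(scene)
  sp <- scene$voxel_spacing; gs <- scene$grid_shape
  origin <- -(gs - 1) / 2 * sp          # grid centred on the flood axis
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(gs[a]) - 1) * sp[a])

  frac_active <- .cylinder_fraction(ax, sp, scene$phantom_center_mm,
                                    scene$active_diameter / 2,
                                    scene$active_height / 2)
  frac_flood <- .cylinder_fraction(ax, sp, c(0, 0, 0),
                                   scene$flood_diameter / 2,
                                   scene$flood_height / 2)
  frac_bg <- pmax(frac_flood - frac_active, 0)

  bg_conc <- switch(scene$background_medium,
                    water = 0, air = 0,
                    activity = scene$background_fraction * scene$active_concentration)
  pet_vals <- scene$active_concentration * frac_active + bg_conc * frac_bg

  hu_bg <- if (scene$background_medium == "air") -1000 else 0
  ct_vals <- 150 * frac_active + hu_bg * frac_bg + (-1000) * (1 - frac_flood)

  pet <- image_volume(pet_vals, spacing = sp, origin = origin,
                      modality = "PET", value_units = "kBq/mL",
                      acquisition_datetime = acquisition_datetime,
                      decay_reference_datetime = decay_reference_datetime)
  ct <- image_volume(ct_vals, spacing = sp, origin = origin,
                     modality = "CT", value_units = "HU",
                     acquisition_datetime = acquisition_datetime)
  list(pet = pet, ct = ct)
}

# Fraction of each voxel inside a z-aligned cylinder, by 2x2x2 subsampling.
# `ax` is the list of voxel-centre coordinates per axis.
.cylinder_fraction <- function(ax, sp, center, radius, half_height) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  frac <- array(0, dim = c(nx, ny, nz))
  for (sx in c(-0.25, 0.25)) for (sy in c(-0.25, 0.25)) {
    dx2 <- (ax[[1]] + sx * sp[1] - center[1])^2
    dy2 <- (ax[[2]] + sy * sp[2] - center[2])^2
    in_xy <- outer(dx2, dy2, `+`) <= radius^2          # nx x ny
    for (sz in c(-0.25, 0.25)) {
      in_z <- abs(ax[[3]] + sz * sp[3] - center[3]) <= half_height
      frac <- frac + outer(in_xy, in_z, `&`)
    }
  }
  frac / 8
}

#' Apply a separable Gaussian point-spread function
#'
#' Convolves the volume with a separable Gaussian whose per-axis sigma is
#' `FWHM / (2 sqrt(2 ln 2))` (~FWHM/2.3548) in mm, converted to voxel
#' units. The kernel is sampled out to 4 sigma and normalised to unit sum,
#' so the total signal is preserved away from grid edges (zero padding
#' leaks at the boundary only).
#'
#' @param vol An [image_volume()].
#' @param psf A [psf_spec()].
#' @return Smoothed [image_volume()].
#' @export
apply_psf <- function(vol, psf) {
  stopifnot(inherits(vol, "image_volume"), inherits(psf, "psf_spec"))
  fwhm <- c(psf$fwhm_transaxial, psf$fwhm_transaxial, psf$fwhm_axial)
  out <- vol
  for (axis in 1:3) {
    if (fwhm[axis] <= 0) next
    sigma_vox <- fwhm[axis] / (2 * sqrt(2 * log(2))) / vol$spacing[axis]
    k <- .gaussian_kernel(sigma_vox)
    out$values <- .convolve_axis(out$values, k, axis)
  }
  out
}

.gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along `axis` via a banded matrix multiply (zero-padded).
.convolve_axis <- function(a, k, axis) {
  perm <- switch(axis, 1:3, c(2, 1, 3), c(3, 2, 1))   # self-inverse swaps
  b <- aperm(a, perm)
  db <- dim(b)
  n <- db[1]
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_along(k)) {
    off <- i - r - 1L
    rows <- seq_len(n)[seq_len(n) + off >= 1 & seq_len(n) + off <= n]
    if (length(rows)) M[cbind(rows, rows + off)] <- k[i]
  }
  dim(b) <- c(n, prod(db[-1]))
  out <- M %*% b
  dim(out) <- db
  aperm(out, perm)
}

#' Add voxel noise to a volume
#'
#' Reproducible given (model, magnitude, seed); the caller's RNG state is
#' left untouched. See [noise_spec()] for the models.
#'
#' @param vol An [image_volume()].
#' @param noise A [noise_spec()].
#' @return Noisy [image_volume()].
#' @export
add_noise <- function(vol, noise) {
  stopifnot(inherits(vol, "image_volume"), inherits(noise, "noise_spec"))
  if (noise$model == "none" || noise$magnitude == 0) return(vol)
  plateau <- stats::quantile(vol$values, 0.999, names = FALSE)
  if (plateau <= 0) plateau <- max(vol$values, 1)
  out <- vol
  out$values <- withr::with_seed(noise$seed, {
    if (noise$model == "gaussian") {
      vol$values + stats::rnorm(length(vol$values),
                                sd = noise$magnitude * plateau)
    } else {                                  # scaled-poisson
      lam <- pmax(vol$values, 0) / plateau * noise$magnitude
      stats::rpois(length(vol$values), lam) / noise$magnitude * plateau
    }
  })
  dim(out$values) <- dim(vol$values)
  out
}

#' Misposition a scene
#'
#' Returns a new scene with the phantom mount rotated about the
#' flood-phantom central axis and/or translated; rendering then proceeds as
#' normal. Rotation moves the mount point around the flood wall (the active
#' cylinder itself is rotationally symmetric about its own axis, so a
#' phantom mounted on the axis is unchanged by rotation). Translation is in
#' mm; "directly upward" in the field of view is +y.
#'
#' @param scene A [phantom_scene()].
#' @param translation_mm Length-3 translation, mm.
#' @param rotation_deg Rotation about the flood axis, degrees.
#' @return A new `phantom_scene` (geometry-checked).
#' @export
misposition <- function(scene, translation_mm = c(0, 0, 0), rotation_deg = 0) {
  stopifnot(inherits(scene, "phantom_scene"))
  th <- rotation_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- scene$phantom_center_mm
  ctr[1:2] <- as.numeric(rot %*% ctr[1:2])
  ctr <- ctr + as.numeric(translation_mm)
  out <- scene
  out$phantom_center_mm <- ctr
  out$rotation_deg <- scene$rotation_deg + rotation_deg
  .check_scene_geometry(out)
  out
}

#' Render a full simulated measurement
#'
#' Convenience chain: [build_scene()], then [apply_psf()] and [add_noise()]
#' on the PET volume (the CT companion stays noiseless — it only feeds the
#' alignment check). An optional global `scale` multiplies the rendered PET
#' values, emulating a net reconstruction/calibration bias.
#'
#' @param scene A [phantom_scene()].
#' @param psf A [psf_spec()], or `NULL` for no smoothing.
#' @param noise A [noise_spec()], or `NULL` for no noise.
#' @param scale Global multiplicative bias applied to the PET volume.
#' @param acquisition_datetime,decay_reference_datetime Timestamps for the
#'   PET volume.
#' @return List with `pet` and `ct` [image_volume()]s.
#' @export
render_scene <- function(scene, psf = psf_spec(), noise = NULL, scale = 1,
                         acquisition_datetime = as.POSIXct(NA),
                         decay_reference_datetime = as.POSIXct(NA)) {
  vols <- build_scene(scene, acquisition_datetime, decay_reference_datetime)
  pet <- vols$pet
  if (!is.null(psf)) pet <- apply_psf(pet, psf)
  if (!is.null(noise)) pet <- add_noise(pet, noise)
  pet$values <- pet$values * scale
  list(pet = pet, ct = vols$ct)
}

#' Write a volume as a readable series
#'
#' Writes NIfTI voxel data plus the `series.json` sidecar that
#' [read_series()] consumes, either as one 3D file or one file per slice
#' (slice entries carry their axial position, so file order is
#' irrelevant). Geometry, units, timestamps and the noise seed are embedded
#' in the sidecar.
#'
#' @param vol An [image_volume()].
#' @param out_dir Output directory (created if needed).
#' @param format `"nifti-3d"` or `"nifti-slices"`.
#' @param seed Noise seed to record in the metadata, if any.
#' @return `out_dir`, invisibly.
#' @export
render_series <- function(vol, out_dir, format = c("nifti-3d", "nifti-slices"),
                          seed = NA_integer_) {
  stopifnot(inherits(vol, "image_volume"))
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "xcalqc-series-v1",
    modality = vol$modality, value_units = vol$value_units,
    spacing_mm = vol$spacing, origin_mm = vol$origin,
    rescale_slope = 1, rescale_intercept = 0,
    generator = "xcalqc simulator"
  )
  if (!is.na(vol$acquisition_datetime)) {
    meta$acquisition_datetime <- format(vol$acquisition_datetime,
                                        "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  if (!is.na(vol$decay_reference_datetime)) {
    meta$decay_reference_datetime <- format(vol$decay_reference_datetime,
                                            "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  if (!is.na(seed)) meta$seed <- seed
  if (format == "nifti-3d") {
    .write_nii(vol$values, vol$spacing, file.path(out_dir, "volume.nii"))
    meta$files <- list(list(file = "volume.nii", z_mm = NA))
  } else {
    nz <- dim(vol$values)[3]
    meta$files <- lapply(seq_len(nz), function(k) {
      f <- sprintf("slice_%03d.nii", k)
      .write_nii(vol$values[, , k, drop = FALSE], vol$spacing,
                 file.path(out_dir, f))
      list(file = f, z_mm = vol$origin[3] + (k - 1) * vol$spacing[3])
    })
  }
  jsonlite::write_json(meta, file.path(out_dir, "series.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(out_dir)
}

.write_nii <- function(arr, spacing, file) {
  im <- RNifti::asNifti(array(arr, dim = dim(arr)))
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, file)
}
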