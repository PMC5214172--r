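test_that("ground-truth scene paints exact concentrations", {
  scene <- phantom_scene()
  vols <- build_scene(scene)
  pet <- vols$pet
  # voxel at the active-region centre holds the nominal concentration
  ctr_idx <- round((scene$phantom_center_mm - pet$origin) / pet$spacing) + 1
  expect_equal(pet$values[ctr_idx[1], ctr_idx[2], ctr_idx[3]], 250)
  # flood voxel outside the active region holds no activity (water background)
  flood_idx <- round((c(0, 40, 0) - pet$origin) / pet$spacing) + 1
  expect_equal(pet$values[flood_idx[1], flood_idx[2], flood_idx[3]], 0)
  # voxel outside the flood phantom is zero
  corner <- pet$values[1, 1, 1]
  expect_equal(corner, 0)

  # radioactive background at 15% of the phantom concentration
  hot_bg <- build_scene(phantom_scene(background_medium = "activity"))$pet
  expect_equal(hot_bg$values[flood_idx[1], flood_idx[2], flood_idx[3]], 37.5)

  # CT companion: epoxy insert ~ +150 HU, water ~ 0, air ~ -1000
  ct <- vols$ct
  expect_equal(ct$values[ctr_idx[1], ctr_idx[2], ctr_idx[3]], 150)
  expect_equal(ct$values[flood_idx[1], flood_idx[2], flood_idx[3]], 0)
  expect_equal(ct$values[1, 1, 1], -1000)
})

test_that("scene geometry violations are rejected", {
  expect_error(phantom_scene(phantom_center_mm = c(0, -90, 0)),
               "outside the flood phantom")
  expect_error(phantom_scene(phantom_center_mm = c(0, 0, 60)),
               "outside the flood phantom")
  expect_error(phantom_scene(flood_diameter = 500, flood_height = 500,
                             phantom_center_mm = c(0, -140, 0)),
               "out of grid")
})

test_that("Gaussian PSF is identity at zero width and matches the closed form", {
  vol <- uniform_volume(0, dims = c(21, 21, 21), spacing = c(2, 2, 2))
  vol$values[11, 11, 11] <- 1

  expect_equal(apply_psf(vol, psf_spec(0, 0))$values, vol$values)

  sm <- apply_psf(vol, psf_spec(8, 4.6))
  # the delta response equals the separable product of sampled Gaussians
  sig <- c(8, 8, 4.6) / (2 * sqrt(2 * log(2))) / 2   # in voxel units
  k1 <- function(s) { r <- max(1, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k / sum(k) }
  kx <- k1(sig[1]); kz <- k1(sig[3])
  rx <- (length(kx) - 1) / 2; rz <- (length(kz) - 1) / 2
  for (off in -2:2) {
    expect_equal(sm$values[11 + off, 11, 11],
                 kx[rx + 1 + off] * kx[rx + 1] * kz[rz + 1],
                 tolerance = 1e-12)
    expect_equal(sm$values[11, 11, 11 + off],
                 kx[rx + 1]^2 * kz[rz + 1 + off],
                 tolerance = 1e-12)
  }
  # kernel has unit mass: total signal preserved away from edges
  expect_equal(sum(sm$values), 1, tolerance = 1e-3)

  # a uniform field is a fixed point of convolution with a unit-mass kernel
  flat <- uniform_volume(5, dims = c(31, 31, 31), spacing = c(2, 2, 2))
  smf <- apply_psf(flat, psf_spec(8, 4.6))
  interior <- smf$values[12:20, 12:20, 12:20]
  expect_equal(unname(range(interior)), c(5, 5), tolerance = 1e-6)
})

test_that("smoothing preserves total activity within 0.1% away from edges", {
  vols <- build_scene(phantom_scene())
  sm <- apply_psf(vols$pet, psf_spec(8, 4.6))
  expect_equal(sum(sm$values), sum(vols$pet$values),
               tolerance = 1e-3)
})

test_that("noise is reproducible, mean-preserving and seed-gated", {
  vols <- default_render()
  pet <- vols$pet
  expect_identical(add_noise(pet, noise_spec("none"))$values, pet$values)
  expect_identical(add_noise(pet, noise_spec("gaussian", 0, seed = 1))$values,
                   pet$values)
  n1 <- add_noise(pet, noise_spec("gaussian", 0.005, seed = 9))
  n2 <- add_noise(pet, noise_spec("gaussian", 0.005, seed = 9))
  n3 <- add_noise(pet, noise_spec("gaussian", 0.005, seed = 10))
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  # caller RNG state is untouched
  withr::with_seed(123, {
    before <- stats::runif(1)
  })
  withr::with_seed(123, {
    invisible(add_noise(pet, noise_spec("gaussian", 0.005, seed = 9)))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
  # scaled-poisson keeps the plateau mean in expectation
  np <- add_noise(pet, noise_spec("scaled-poisson", 5000, seed = 4))
  roi <- whole_voxel_roi(np, locate_active_center(np), box_mm = 15)
  expect_equal(roi_statistics(np, roi)$mean, 250, tolerance = 0.02)
  expect_error(noise_spec("gaussian", 0.005), "seed")
})

test_that("misposition transforms the scene geometry as requested", {
  base <- phantom_scene()
  expect_equal(misposition(base)$phantom_center_mm, base$phantom_center_mm)

  # +40 mm upward translation moves the rendered centroid by 40 mm
  up <- misposition(base, translation_mm = c(0, 40, 0))
  expect_equal(up$phantom_center_mm, c(0, -30, 0))
  ctr <- locate_active_center(render_scene(up)$pet)
  expect_lt(abs(ctr[2] - (-30)), 2.7 / 2)

  # rotation about the flood axis moves the mount around the wall
  rot <- misposition(base, rotation_deg = 90)
  expect_equal(rot$phantom_center_mm, c(70, 0, 0), tolerance = 1e-9)

  # a phantom on the flood axis is invariant under rotation about it
  centred <- phantom_scene(phantom_center_mm = c(0, 0, 0))
  r90 <- misposition(centred, rotation_deg = 90)
  expect_equal(build_scene(r90)$pet$values, build_scene(centred)$pet$values)

  expect_error(misposition(base, translation_mm = c(0, -10, 0)),
               "outside the flood")
})

test_that("rendered noise at the default level keeps ROI uniformity under 2%", {
  for (seed in c(1, 2)) {
    v <- render_scene(phantom_scene(),
                      noise = noise_spec("gaussian", 0.005, seed = seed))
    ctr <- locate_active_center(v$pet)
    u <- roi_statistics(v$pet, whole_voxel_roi(v$pet, ctr, 15))$u
    expect_lt(u, 2)
  }
})
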