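test_that("identity control points give the identity transform with zero residual", {
  pts <- cbind(c(1, 50, 50, 200), c(1, 10, 300, 150))
  t <- fit_transform(control_points(pts, pts))
  expect_equal(t$A, diag(2), tolerance = 1e-12)
  expect_equal(t$b, c(0, 0), tolerance = 1e-12)
  expect_equal(t$rms_residual_px, 0, tolerance = 1e-12)
})

test_that("a known scale + translation is recovered to machine precision", {
  set.seed(61)
  rgbp <- cbind(runif(130, 1, 4000), runif(130, 1, 6000))
  nirp <- 0.25 * rgbp + matrix(c(10, 20), 130, 2, byrow = TRUE)
  t <- fit_transform(control_points(rgbp, nirp))
  expect_lt(max(abs(t$A - diag(0.25, 2))), 1e-9)
  expect_lt(max(abs(t$b - c(10, 20))), 1e-9)
  expect_lt(t$rms_residual_px, 1e-9)
})

test_that("fit residual reflects the control-point noise level", {
  set.seed(62)
  rms <- replicate(10, {
    rgbp <- cbind(runif(130, 1, 4000), runif(130, 1, 6000))
    nirp <- 0.25 * rgbp + matrix(c(10, 20), 130, 2, byrow = TRUE) +
      matrix(rnorm(260, 0, 0.5), 130, 2)
    fit_transform(control_points(rgbp, nirp))$rms_residual_px
  })
  expect_equal(mean(rms), 0.5, tolerance = 0.1)
})

test_that("degenerate control-point sets are rejected", {
  expect_error(control_points(cbind(1:2, 1:2), cbind(1:2, 1:2)), "at least 3")
  line <- cbind(1:5, 2 * (1:5))
  expect_error(fit_transform(control_points(line, line)), "collinear")
  dup <- rbind(c(1, 1), c(1, 1), c(2, 5))
  expect_error(control_points(dup, dup), "duplicate")
})

test_that("mask transfer is exact under identity and errors off-frame", {
  m <- make_rect_mask(10, 10, canvas = c(30, 30), at = c(8, 8))
  ident <- planar_transform(diag(2), c(0, 0))
  expect_identical(transfer_mask(m, ident, c(30, 30)), m)
  off <- planar_transform(diag(2), c(500, 500))
  expect_error(transfer_mask(m, off, c(30, 30)), "outside")
})

test_that("mask transferred via the true camera affine overlaps the NIR truth", {
  sc <- render_scene(plant_spec(stress = 0.4, canvas_height_px = 160L,
                                canvas_width_px = 200L, leaf_length_px = 48,
                                rng_seed = 51))
  mask <- segment_plant(sc$rgb)
  warped <- transfer_mask(mask, sc$rgb_to_nir_truth, dim(sc$nir))
  jac <- sum(warped & sc$mask_truth_nir) / sum(warped | sc$mask_truth_nir)
  expect_gte(jac, 0.9)
})

test_that("NIR water index is the reciprocal mean and is homogeneous", {
  full <- matrix(TRUE, 6, 6)
  expect_equal(nir_intensity(matrix(0.5, 6, 6), full), 2)
  expect_equal(nir_intensity(matrix(0.25, 6, 6), full), 4) # drier reads higher
  r <- matrix(runif(36, 0.1, 0.9), 6, 6)
  for (cc in c(0.5, 2)) {
    expect_equal(nir_intensity(cc * r, full), nir_intensity(r, full) / cc,
                 tolerance = 1e-12)
  }
  expect_error(nir_intensity(matrix(0, 6, 6), full), "zero")
})

test_that("plant temperature is the mean over the mask", {
  full <- matrix(TRUE, 4, 4)
  expect_equal(plant_temperature(matrix(24.7, 4, 4), full), 24.7)
  half <- matrix(c(24, 26), 4, 4)
  expect_equal(plant_temperature(half, full), 25)
  expect_error(plant_temperature(half, matrix(FALSE, 4, 4)), "empty")
})

test_that("fluorescence parameters reproduce the healthy-plant ratios", {
  f0 <- matrix(0.2, 5, 5); fm <- matrix(1.0, 5, 5)
  fl <- fluorescence_params(f0, fm)
  expect_equal(fl$fv_mean, 0.8)
  expect_equal(fl$fv_over_fm, 0.8)
  expect_equal(fl$fm_over_f0, 5.0)
  expect_equal(fl$fluorescence_area_px, 25L)

  # zero variable fluorescence is a valid, fully quenched reading
  same <- fluorescence_params(matrix(0.4, 3, 3), matrix(0.4, 3, 3))
  expect_equal(same$fv_mean, 0)
  expect_equal(same$fv_over_fm, 0)

  # physically impossible pixels (fm < f0) are excluded and counted
  fm2 <- fm; fm2[1, 1] <- 0.1
  fl2 <- fluorescence_params(f0, fm2)
  expect_equal(fl2$n_excluded_px, 1L)
  expect_equal(fl2$fv_over_fm, 0.8)
})

test_that("the fluorescence area follows the Fm threshold rule", {
  fm <- matrix(0, 10, 10); fm[3:6, 3:6] <- 0.9
  f0 <- matrix(0, 10, 10); f0[3:6, 3:6] <- 0.2
  fl <- fluorescence_params(f0, fm, cfg = pheno_config(fluor_area_frac = 0.05))
  expect_equal(fl$fluorescence_area_px, 16L)
  expect_error(fluorescence_params(matrix(0, 2, 2), matrix(0, 2, 3)), "size")
})

test_that("Fv/Fm stays within [0, 1] for arbitrary valid frames", {
  set.seed(71)
  for (i in 1:20) {
    f0 <- matrix(runif(64, 0.05, 0.5), 8, 8)
    fm <- f0 + matrix(runif(64, 0, 1), 8, 8)
    fl <- fluorescence_params(f0, fm)
    expect_gte(fl$fv_over_fm, 0); expect_lte(fl$fv_over_fm, 1)
  }
})
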