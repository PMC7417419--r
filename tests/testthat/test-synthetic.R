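# Small canvas used throughout: keeps renders fast while leaving room for
# the drooped-leaf excursion.
small_spec <- function(...) {
  plant_spec(canvas_height_px = 160L, canvas_width_px = 200L,
             leaf_length_px = 48, ...)
}

test_that("rendering is deterministic for a fixed spec and seed", {
  a <- render_scene(small_spec(stress = 0.4, rng_seed = 9))
  b <- render_scene(small_spec(stress = 0.4, rng_seed = 9))
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$mask_truth, b$mask_truth)
  expect_identical(a$nir, b$nir)
  expect_identical(a$ir_c, b$ir_c)
  expect_identical(a$fm, b$fm)
})

test_that("the truth mask is exactly the non-background RGB pixels", {
  sc <- render_scene(small_spec(stress = 0.3, rng_seed = 2),
                     render_options(noise_sd = 0))
  bg <- sc$rgb[1, 1, ] # border pixels are always background (8-bit quantized)
  nonbg <- sc$rgb[, , 1] != bg[1] | sc$rgb[, , 2] != bg[2] | sc$rgb[, , 3] != bg[3]
  expect_identical(unname(nonbg), unname(sc$mask_truth))
  expect_gt(sum(sc$mask_truth), 0)
  # no foreground on the canvas border
  expect_false(any(sc$mask_truth[1, ]) || any(sc$mask_truth[nrow(sc$mask_truth), ]) ||
               any(sc$mask_truth[, 1]) || any(sc$mask_truth[, ncol(sc$mask_truth)]))
})

test_that("an unstressed plant is green with healthy photochemistry", {
  sc <- render_scene(small_spec(stress = 0, droop = 0, rng_seed = 5))
  frac <- color_fractions(hue_histogram(sc$rgb, sc$mask_truth))
  expect_lt(frac["yellow_fraction"], 0.05)
  fl <- fluorescence_params(sc$f0, sc$fm)
  expect_equal(fl$fv_over_fm, 0.8, tolerance = 0.02)
  expect_equal(fl$fm_over_f0, 5.0, tolerance = 0.2)
})

test_that("canopy warming equals the configured slope at full stress", {
  opts <- render_options(ir_noise_sd = 0, leaf_roll_max = 0)
  s0 <- render_scene(small_spec(stress = 0, droop = 0.3, rng_seed = 4), opts)
  s1 <- render_scene(small_spec(stress = 1, droop = 0.3,
                                water_content = 0.5, rng_seed = 4), opts)
  expect_identical(s0$mask_truth, s1$mask_truth) # same geometry
  d <- plant_temperature(s1$ir_c, s1$mask_truth_nir) -
    plant_temperature(s0$ir_c, s0$mask_truth_nir)
  expect_equal(d, render_options()$ir_k_c, tolerance = 1e-9)
})

test_that("projected area is stable across render seeds", {
  areas <- vapply(1:20, function(s) {
    sum(render_scene(small_spec(stress = 0.2, rng_seed = s))$mask_truth)
  }, numeric(1))
  expect_true(all(abs(areas - mean(areas)) / mean(areas) < 0.10))
})

test_that("stress drives every modality monotonically on the stress grid", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  yellow <- temp <- recip_nir <- fvfm <- numeric(length(grid))
  for (i in seq_along(grid)) {
    sc <- render_scene(small_spec(stress = grid[i], rng_seed = 11))
    yellow[i] <- color_fractions(hue_histogram(sc$rgb, sc$mask_truth))["yellow_fraction"]
    temp[i] <- plant_temperature(sc$ir_c, sc$mask_truth_nir)
    recip_nir[i] <- nir_intensity(sc$nir, sc$mask_truth_nir)
    fvfm[i] <- fluorescence_params(sc$f0, sc$fm)$fv_over_fm
    expect_true(all(sc$fm >= sc$f0)) # pixelwise, plant and background
  }
  expect_true(all(diff(yellow) > 0))
  expect_true(all(diff(temp) > 0))
  expect_true(all(diff(recip_nir) < 0)) # water index falls as stress rises
  expect_true(all(diff(fvfm) < 0))
})

test_that("degenerate specs are rejected", {
  expect_error(plant_spec(tiller_count = 0), "positive")
  expect_error(
    render_scene(plant_spec(canvas_height_px = 60, canvas_width_px = 60,
                            leaf_length_px = 50)),
    "too small")
})

test_that("a lossless pot holds weight and never triggers irrigation", {
  s <- simulate_weighing_series(800, 0, 0, 0, days = 2, mode = "deviation",
                                noise_sd_g = 0.5, rng_seed = 8)
  expect_equal(nrow(s$events), 0L)
  expect_lt(sd(s$weight_g), 0.6)            # noise only, no trend
  expect_lt(abs(mean(s$weight_g) - 800), 0.1)
})

test_that("deviation-mode refills trigger at the 5% deficit of the 800 g target", {
  s <- simulate_weighing_series(800, 45, 30, 0.25, days = 7, mode = "deviation",
                                target_weight_g = 800,
                                refill_threshold_frac = 0.05, rng_seed = 12)
  expect_gt(nrow(s$events), 0L)
  idx <- match(as.numeric(s$events$time), as.numeric(s$time))
  expect_true(all(s$weight_g[idx] <= 760))
  # recorded weight just before each refill is still above the trigger
  expect_true(all(s$weight_g[idx - 1L] > 760))
})

test_that("weighing simulation validates its inputs", {
  expect_error(simulate_weighing_series(800, 10, 10, 0.1, days = 0), "positive")
  expect_error(simulate_weighing_series(800, -1, 10, 0.1, days = 1),
               "nonnegative")
})

test_that("cohort generation writes a complete, reproducible manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_cohort(1, 1, days = 2, rng_seed = 31, out_dir = d1)
  expect_equal(nrow(m1), 4L)
  for (col in c("rgb_path", "nir_path", "ir_path", "f0_path", "fm_path",
                "mask_path")) {
    expect_true(all(file.exists(file.path(d1, m1[[col]]))))
  }
  generate_cohort(1, 1, days = 2, rng_seed = 31, out_dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
})

test_that("susceptible plants end the drought more stressed than tolerant ones", {
  d <- withr::local_tempdir()
  m <- generate_cohort(2, 2, days = 6, rng_seed = 13, out_dir = d,
                       canvas_height_px = 160L, canvas_width_px = 200L,
                       leaf_length_px = 48)
  final <- m[m$day == max(m$day), ]
  expect_lt(mean(final$stress[final$group == "tolerant"]),
            mean(final$stress[final$group == "susceptible"]))
})
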