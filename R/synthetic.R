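# Synthetic multimodal phenome generator. Renders side-view rice-like
# shoots whose geometry (leaf droop), color (green-to-yellow hue shift),
# NIR reflectance, canopy temperature and fluorescence yield all follow a
# latent drought-stress level, together with gravimetric pot-weighing
# series. Everything is seeded and deterministic, so the whole analysis
# pipeline can be exercised and validated without instrument data.

# Run expr under a temporary RNG state; never leaks into the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Specification of one synthetic plant
#'
#' The latent ground truth driving every rendered modality. `stress` is the
#' drought severity in `[0,1]`; unless overridden, leaf droop follows
#' stress and tissue water content is its complement.
#'
#' @param genotype_label free-text label carried into manifests.
#' @param day integer day index (days after sowing).
#' @param tiller_count,leaf_count_per_tiller positive integers; their
#'   product is the number of rendered leaves.
#' @param leaf_length_px leaf length in pixels.
#' @param stress latent drought severity in `[0,1]` (clamped).
#' @param droop leaf droop in `[0,1]` (0 erect, 1 fully wilted); defaults
#'   to `stress`.
#' @param water_content tissue water content in `[0,1]`; defaults to
#'   `1 - stress`.
#' @param base_temperature_c canopy temperature of an unstressed plant
#'   (degrees Celsius).
#' @param canvas_height_px,canvas_width_px RGB canvas size.
#' @param rng_seed integer seed; identical specs render identical scenes.
#' @return Object of class `plant_spec`.
#' @export
#' @examples
#' plant_spec(stress = 0.5, rng_seed = 7)
plant_spec <- function(genotype_label = "synthetic",
                       day = 1L,
                       tiller_count = 3L,
                       leaf_count_per_tiller = 3L,
                       leaf_length_px = 90,
                       stress = 0,
                       droop = NULL,
                       water_content = NULL,
                       base_temperature_c = 24.7,
                       canvas_height_px = 300L,
                       canvas_width_px = 400L,
                       rng_seed = 1L) {
  if (tiller_count < 1L || leaf_count_per_tiller < 1L) {
    stop("tiller_count and leaf_count_per_tiller must be positive",
         call. = FALSE)
  }
  if (leaf_length_px <= 0) stop("leaf_length_px must be positive", call. = FALSE)
  stress <- clamp(stress, 0, 1)
  if (is.null(droop)) droop <- stress
  droop <- clamp(droop, 0, 1)
  if (is.null(water_content)) water_content <- 1 - stress
  water_content <- clamp(water_content, 0, 1)
  structure(list(
    genotype_label = genotype_label,
    day = as.integer(day),
    tiller_count = as.integer(tiller_count),
    leaf_count_per_tiller = as.integer(leaf_count_per_tiller),
    leaf_length_px = leaf_length_px,
    stress = stress,
    droop = droop,
    water_content = water_content,
    base_temperature_c = base_temperature_c,
    canvas_height_px = as.integer(canvas_height_px),
    canvas_width_px = as.integer(canvas_width_px),
    rng_seed = as.integer(rng_seed)
  ), class = "plant_spec")
}

#' Rendering options for the synthetic scene
#'
#' The free parameters of the renderer, i.e. everything the field's
#' published cohort statistics do not pin down: noise magnitudes, the
#' modality response curves and the NIR camera frame.
#'
#' @param noise_sd additive Gaussian RGB pixel noise (8-bit scale divided
#'   out; default 2/255).
#' @param hue_yellow_mean,hue_yellow_sd,hue_green_mean,hue_green_sd hue
#'   mixture components in degrees (yellow ~58, green ~122).
#' @param yellow_weight_range mixing weight of the yellow component at
#'   stress 0 and stress 1.
#' @param leaf_roll_max fraction of rendered leaf length lost at full
#'   stress: rice leaves roll and fold under drought, collapsing the
#'   projected side-view area, so canopy area shrinks as water status
#'   declines. Default 0.35.
#' @param ir_k_c canopy warming at full stress (degrees Celsius).
#' @param ir_ambient_c background temperature (degrees Celsius).
#' @param ir_noise_sd per-pixel IR noise (degrees Celsius).
#' @param nir_index_wet,nir_index_dry reciprocal NIR water index (1 / mean
#'   reflectance at the 1450 nm water-absorption band) of fully hydrated
#'   and fully desiccated tissue. The index is the scale reported by NIR
#'   phenotyping rigs and is taken linear in tissue water content; water
#'   absorbs at this band, so wet tissue records low raw intensity and a
#'   high index. Defaults 7.1 and 2.5 span the range reported for rice
#'   shoots.
#' @param nir_background,nir_noise_sd NIR background level and pixel noise.
#' @param f0_level minimal fluorescence of plant tissue (relative units).
#' @param yield_healthy,yield_stressed PSII maximum quantum yield at stress
#'   0 and 1 (healthy dark-adapted leaves sit near 0.8).
#' @param yield_noise_sd per-pixel yield noise.
#' @param nir_scale,nir_offset the true RGB-to-NIR affine: NIR frame is the
#'   RGB frame downscaled by `nir_scale` and shifted by `nir_offset`
#'   (row, col), emulating the resolution mismatch of the two cameras.
#' @param background_rgb background gray level of the RGB canvas.
#' @return List of class `render_options`.
#' @export
render_options <- function(noise_sd = 2 / 255,
                           hue_yellow_mean = 58, hue_yellow_sd = 6,
                           hue_green_mean = 122, hue_green_sd = 8,
                           yellow_weight_range = c(0.02, 0.60),
                           leaf_roll_max = 0.35,
                           ir_k_c = 3.0,
                           ir_ambient_c = 26.0,
                           ir_noise_sd = 0.05,
                           nir_index_wet = 7.1, nir_index_dry = 2.5,
                           nir_background = 0.04, nir_noise_sd = 0.02,
                           f0_level = 0.15,
                           yield_healthy = 0.80, yield_stressed = 0.50,
                           yield_noise_sd = 0.01,
                           nir_scale = 0.25, nir_offset = c(3, 5),
                           background_rgb = 0.12) {
  structure(as.list(environment()), class = "render_options")
}

#' Render a multimodal synthetic plant scene
#'
#' Leaves are tapered quadratic curves fanning out from a stem base; droop
#' rotates the distal half of each leaf downward, which raises the mask's
#' center of mass and widens its horizontal extent, as wilting does. Hue is
#' drawn per plant pixel from a yellow/green mixture whose yellow weight
#' grows with stress; NIR reflectance rises as water content falls (wet
#' tissue absorbs at 1450 nm and records LOW intensity); canopy temperature
#' is `base_temperature_c + ir_k_c * stress`; fluorescence frames satisfy
#' `fm = f0 / (1 - yield)` with yield declining in stress, so `fm >= f0`
#' everywhere on the plant.
#'
#' The NIR, IR and fluorescence rasters share one frame related to the RGB
#' frame by the ground-truth affine `rgb_to_nir_truth` (downscale plus
#' translation). Rendering is fully deterministic for a fixed spec.
#'
#' @param spec a [plant_spec()].
#' @param opts a [render_options()].
#' @return Object of class `rendered_scene`: `rgb` (`H x W x 3`, 8-bit
#'   quantized), `mask_truth` (logical), `nir`, `ir_c`, `f0`, `fm`
#'   (matrices in the NIR frame), `mask_truth_nir`, `rgb_to_nir_truth`
#'   (a [planar_transform()]), and the `spec`.
#' @export
#' @examples
#' scene <- render_scene(plant_spec(stress = 0.5, rng_seed = 3))
#' sum(scene$mask_truth)
render_scene <- function(spec, opts = render_options()) {
  stopifnot(inherits(spec, "plant_spec"))
  h <- spec$canvas_height_px; w <- spec$canvas_width_px
  # erect leaves need ~L above the base, fully drooped tips ~0.35 L below it,
  # and the lateral fan spans ~1.5 L; margins cover stamp radius and jitter
  if (h < 1.45 * spec$leaf_length_px + 24 || w < 1.7 * spec$leaf_length_px + 24) {
    stop(sprintf(
      "canvas %dx%d too small for leaf length %.0f px (need h >= 1.45 L + 24, w >= 1.7 L + 24)",
      h, w, spec$leaf_length_px), call. = FALSE)
  }
  with_seed(spec$rng_seed, {
    mask <- render_shoot_mask(spec, opts)
    rgb <- render_rgb(mask, spec, opts)
    truth <- planar_transform(diag(opts$nir_scale, 2), opts$nir_offset)
    nir_shape <- c(
      ceiling(opts$nir_scale * h) + 2 * ceiling(opts$nir_offset[1]),
      ceiling(opts$nir_scale * w) + 2 * ceiling(opts$nir_offset[2])
    )
    mask_nir <- transfer_mask(mask, truth, nir_shape)

    n_nir <- sum(mask_nir)
    nir <- matrix(opts$nir_background, nir_shape[1], nir_shape[2])
    nir_index <- opts$nir_index_dry +
      (opts$nir_index_wet - opts$nir_index_dry) * spec$water_content
    nir[mask_nir] <- clamp(1 / nir_index + stats::rnorm(n_nir, 0, opts$nir_noise_sd),
                           0, 1)

    ir <- matrix(opts$ir_ambient_c, nir_shape[1], nir_shape[2])
    ir[mask_nir] <- spec$base_temperature_c + opts$ir_k_c * spec$stress +
      stats::rnorm(n_nir, 0, opts$ir_noise_sd)

    f0 <- matrix(0, nir_shape[1], nir_shape[2])
    fm <- matrix(0, nir_shape[1], nir_shape[2])
    f0[mask_nir] <- opts$f0_level
    yield <- clamp(
      opts$yield_healthy - (opts$yield_healthy - opts$yield_stressed) * spec$stress +
        stats::rnorm(n_nir, 0, opts$yield_noise_sd),
      0.05, 0.95)
    fm[mask_nir] <- opts$f0_level / (1 - yield)

    structure(list(
      rgb = rgb, mask_truth = mask,
      nir = nir, ir_c = ir, f0 = f0, fm = fm,
      mask_truth_nir = mask_nir,
      rgb_to_nir_truth = truth,
      spec = spec
    ), class = "rendered_scene")
  })
}

# Tapered-curve shoot geometry; returns the logical foreground mask.
# Stress rolls the leaves (shortening the projected length); droop bends
# the distal half of each leaf downward.
render_shoot_mask <- function(spec, opts = render_options()) {
  h <- spec$canvas_height_px; w <- spec$canvas_width_px
  n_leaves <- spec$tiller_count * spec$leaf_count_per_tiller
  L <- spec$leaf_length_px * (1 - opts$leaf_roll_max * spec$stress)
  base <- c(h - ceiling(0.35 * spec$leaf_length_px) - 8, round((w + 1) / 2))
  # fan of base angles (radians from vertical, signed left/right)
  a0 <- seq(-50, 50, length.out = n_leaves) * pi / 180 +
    stats::rnorm(n_leaves, 0, 1.5 * pi / 180)
  # full droop swings tips to 115 degrees from vertical: below horizontal
  # (leaf drying lowers the mass center) and farther out laterally than the
  # erect fan (wilting widens the horizontal extent)
  a2 <- sign(a0) * (abs(a0) + spec$droop * (115 * pi / 180 - abs(a0)))
  dir_vec <- function(a) cbind(-cos(a), sin(a)) # (drow, dcol) per angle
  base_jit <- cbind(stats::rnorm(n_leaves, 0, 0.8), stats::rnorm(n_leaves, 0, 1))
  leaf_len <- L * clamp(1 + stats::rnorm(n_leaves, 0, 0.03), 0.94, 1.06)

  nt <- max(40L, ceiling(2.2 * L))
  tt <- seq(0, 1, length.out = nt)
  radius <- 3.2 * (1 - tt) + 1.4 * tt
  rows <- integer(0); cols <- integer(0)
  for (k in seq_len(n_leaves)) {
    p0 <- base + base_jit[k, ]
    p1 <- p0 + 0.7 * leaf_len[k] * dir_vec(a0[k])
    p2 <- p0 + 0.55 * leaf_len[k] * dir_vec(a0[k]) +
      0.45 * leaf_len[k] * dir_vec(a2[k])
    br <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
    bc <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
    for (i in seq_len(nt)) {
      r <- radius[i]
      ri <- ceiling(r)
      dr <- rep(-ri:ri, times = 2 * ri + 1)
      dc <- rep(-ri:ri, each = 2 * ri + 1)
      keep <- dr * dr + dc * dc <= r * r
      rows <- c(rows, round(br[i]) + dr[keep])
      cols <- c(cols, round(bc[i]) + dc[keep])
    }
  }
  if (min(rows) <= 1L || max(rows) >= h || min(cols) <= 1L || max(cols) >= w) {
    stop("rendered plant does not fit inside the canvas; enlarge the canvas ",
         "or shorten the leaves", call. = FALSE)
  }
  mask <- matrix(FALSE, h, w)
  mask[cbind(rows, cols)] <- TRUE
  mask
}

# Per-pixel hue mixture -> 8-bit RGB canvas with additive noise.
render_rgb <- function(mask, spec, opts) {
  h <- nrow(mask); w <- ncol(mask)
  n <- sum(mask)
  wy <- opts$yellow_weight_range[1] +
    diff(opts$yellow_weight_range) * spec$stress
  is_yellow <- stats::runif(n) < wy
  hue <- ifelse(is_yellow,
                stats::rnorm(n, opts$hue_yellow_mean, opts$hue_yellow_sd),
                stats::rnorm(n, opts$hue_green_mean, opts$hue_green_sd))
  hue <- clamp(hue, 5, 175)
  sat <- clamp(stats::rnorm(n, 0.78, 0.06), 0.40, 1)
  val <- clamp(stats::rnorm(n, 0.55, 0.06), 0.25, 0.90)
  cols <- grDevices::col2rgb(grDevices::hsv(hue / 360, sat, val)) / 255

  rgb <- array(opts$background_rgb, dim = c(h, w, 3))
  idx <- which(mask)
  rgb[idx] <- cols[1, ]
  rgb[idx + h * w] <- cols[2, ]
  rgb[idx + 2 * h * w] <- cols[3, ]
  if (opts$noise_sd > 0) {
    rgb <- rgb + stats::rnorm(length(rgb), 0, opts$noise_sd)
  }
  round(clamp(rgb, 0, 1) * 255) / 255
}

#' Simulate a gravimetric pot-weighing series
#'
#' Pot weight decays by soil evaporation plus leaf-area-proportional
#' transpiration, with Gaussian observation noise, sampled on a regular
#' clock (default 1-minute intervals, the resolution of gravimetric
#' platforms). Transpiration is expressed on the percent-of-initial-weight
#' basis used by the water-budget analysis: grams lost per day equal
#' `tr_true_pct_per_cm2_day / 100 * leaf_area_cm2 * initial_weight_g`, so
#' [transpiration_rate()] applied to the simulated planted/empty pair
#' recovers `tr_true_pct_per_cm2_day`.
#'
#' In `deviation` mode, whenever the recorded weight drops to
#' `target_weight_g * (1 - refill_threshold_frac)` or below, an irrigation
#' event restores the true weight to `target_weight_g` and is logged (the
#' default 800 g target with a 5% deficit trigger refills at 760 g).
#' `none` mode never refills.
#'
#' @param initial_weight_g starting pot weight (g).
#' @param soil_evap_rate_g_per_day soil evaporation (g/day), nonnegative.
#' @param leaf_area_cm2 leaf area (cm^2), nonnegative.
#' @param tr_true_pct_per_cm2_day true transpiration rate (percent of
#'   initial weight per cm^2 per day), nonnegative.
#' @param days duration (whole days), positive.
#' @param mode `"none"` or `"deviation"`.
#' @param target_weight_g refill target (deviation mode).
#' @param refill_threshold_frac deficit fraction triggering a refill.
#' @param dt_minutes sampling interval (minutes), positive.
#' @param noise_sd_g observation noise sd (g); default 0.5.
#' @param rng_seed integer seed.
#' @param pot_kind `"planted"` or `"empty"` label for the series.
#' @return A [weighing_series()] starting 2024-03-01 11:00 UTC.
#' @export
#' @examples
#' s <- simulate_weighing_series(800, 20, 30, 0.2, days = 3, rng_seed = 1)
#' irrigation_summary(s)
simulate_weighing_series <- function(initial_weight_g = 800,
                                     soil_evap_rate_g_per_day = 20,
                                     leaf_area_cm2 = 30,
                                     tr_true_pct_per_cm2_day = 0.2,
                                     days = 7L,
                                     mode = c("none", "deviation"),
                                     target_weight_g = 800,
                                     refill_threshold_frac = 0.05,
                                     dt_minutes = 1L,
                                     noise_sd_g = 0.5,
                                     rng_seed = 1L,
                                     pot_kind = c("planted", "empty")) {
  mode <- match.arg(mode)
  pot_kind <- match.arg(pot_kind)
  if (days <= 0 || dt_minutes <= 0) {
    stop("days and dt_minutes must be positive", call. = FALSE)
  }
  if (soil_evap_rate_g_per_day < 0 || tr_true_pct_per_cm2_day < 0 ||
      leaf_area_cm2 < 0) {
    stop("rates and leaf area must be nonnegative", call. = FALSE)
  }
  n <- as.integer(days * 24 * 60 / dt_minutes) + 1L
  start <- as.POSIXct("2024-03-01 11:00:00", tz = "UTC")
  time <- start + (seq_len(n) - 1L) * dt_minutes * 60
  loss_per_day <- soil_evap_rate_g_per_day +
    tr_true_pct_per_cm2_day / 100 * leaf_area_cm2 * initial_weight_g
  step_loss <- loss_per_day * dt_minutes / (24 * 60)
  trigger <- target_weight_g * (1 - refill_threshold_frac)

  with_seed(rng_seed, {
    noise <- stats::rnorm(n, 0, noise_sd_g)
    w_true <- numeric(n)
    w_obs <- numeric(n)
    ev_time <- integer(0); ev_added <- numeric(0)
    cur <- initial_weight_g
    for (i in seq_len(n)) {
      if (i > 1L) cur <- cur - step_loss
      if (cur <= 0) {
        stop("pot dried out (nonpositive weight); shorten the run or lower ",
             "the loss rates", call. = FALSE)
      }
      w_obs[i] <- cur + noise[i]
      if (mode == "deviation" && w_obs[i] <= trigger) {
        ev_time <- c(ev_time, i)
        ev_added <- c(ev_added, target_weight_g - cur)
        cur <- target_weight_g
      }
      w_true[i] <- cur
    }
    events <- data.frame(time = time[ev_time], added_g = ev_added)
    weighing_series(time, w_obs, events, pot_kind)
  })
}

#' Generate a labeled synthetic drought cohort on disk
#'
#' Renders one scene per plant per day for a drought-tolerant and a
#' drought-susceptible group and writes the rasters (RGB as PNG; NIR, IR,
#' F0, Fm as 32-bit float TIFF, temperature encoded with scale 100), the
#' ground-truth masks, a 130-point registration control-point file, and a
#' manifest CSV with the latent ground truth. Susceptible plants follow a
#' steeper stress ramp than tolerant ones, so by the final day the
#' susceptible group has strictly higher mean stress. Identical seeds give
#' byte-identical manifests.
#'
#' @param n_tolerant,n_susceptible plants per group.
#' @param days number of consecutive days imaged.
#' @param rng_seed integer seed.
#' @param out_dir output directory (created if missing).
#' @param canvas_height_px,canvas_width_px,leaf_length_px scene geometry
#'   (defaults sized for quick test cohorts).
#' @param stress_rate_tolerant,stress_rate_susceptible per-day stress ramp
#'   slopes for the two groups.
#' @param opts a [render_options()].
#' @param px_per_cm2 pixel-to-leaf-area conversion recorded in the
#'   manifest.
#' @return The manifest as a data frame (also written to
#'   `out_dir/manifest.csv`), invisibly columns: plant_id, genotype, group,
#'   day, stress, water_content, leaf_area_cm2 and the five raster paths.
#' @export
generate_cohort <- function(n_tolerant, n_susceptible, days, rng_seed, out_dir,
                            canvas_height_px = 220L, canvas_width_px = 300L,
                            leaf_length_px = 64,
                            stress_rate_tolerant = 0.05,
                            stress_rate_susceptible = 0.13,
                            opts = render_options(),
                            px_per_cm2 = 100) {
  if (n_tolerant < 0L || n_susceptible < 0L || n_tolerant + n_susceptible < 1L) {
    stop("need at least one plant", call. = FALSE)
  }
  if (days < 1L) stop("days must be positive", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir, call. = FALSE)

  groups <- c(rep("tolerant", n_tolerant), rep("susceptible", n_susceptible))
  n_plants <- length(groups)
  plant_ids <- sprintf("%s_%02d", ifelse(groups == "tolerant", "tol", "sus"),
                       unlist(lapply(c(n_tolerant, n_susceptible)[c(n_tolerant, n_susceptible) > 0],
                                     seq_len)))
  rate_base <- ifelse(groups == "tolerant", stress_rate_tolerant,
                      stress_rate_susceptible)
  rate_mult <- with_seed(rng_seed, stats::rnorm(n_plants, 1, 0.08))
  rate <- rate_base * clamp(rate_mult, 0.7, 1.3)

  rows <- vector("list", n_plants * days)
  k <- 0L
  for (p in seq_len(n_plants)) {
    len_d <- leaf_length_px
    for (d in seq_len(days)) {
      stress <- clamp(rate[p] * (d - 1), 0, 1)
      # daily elongation slows with stress: drought stalls canopy growth
      if (d > 1L) len_d <- len_d * (1 + 0.03 * (1 - stress))
      spec <- plant_spec(
        genotype_label = paste0("synthetic_", groups[p]),
        day = d,
        leaf_length_px = len_d,
        stress = stress,
        canvas_height_px = canvas_height_px,
        canvas_width_px = canvas_width_px,
        rng_seed = rng_seed + 1000L * p + d
      )
      scene <- render_scene(spec, opts)
      stem <- sprintf("%s_d%02d", plant_ids[p], d)
      paths <- c(
        rgb = paste0(stem, "_rgb.png"),
        mask = paste0(stem, "_mask.png"),
        nir = paste0(stem, "_nir.tif"),
        ir = paste0(stem, "_ir.tif"),
        f0 = paste0(stem, "_f0.tif"),
        fm = paste0(stem, "_fm.tif")
      )
      write_raster(scene$rgb, file.path(out_dir, paths["rgb"]))
      write_mask(scene$mask_truth, file.path(out_dir, paths["mask"]))
      write_raster(scene$nir, file.path(out_dir, paths["nir"]))
      write_raster(scene$ir_c, file.path(out_dir, paths["ir"]), scale = 100)
      write_raster(scene$f0, file.path(out_dir, paths["f0"]))
      write_raster(scene$fm, file.path(out_dir, paths["fm"]))
      k <- k + 1L
      rows[[k]] <- data.frame(
        plant_id = plant_ids[p], genotype = spec$genotype_label,
        group = groups[p], day = d,
        stress = stress, water_content = 1 - stress,
        leaf_area_cm2 = sum(scene$mask_truth) / px_per_cm2,
        rgb_path = unname(paths["rgb"]), mask_path = unname(paths["mask"]),
        nir_path = unname(paths["nir"]), ir_path = unname(paths["ir"]),
        f0_path = unname(paths["f0"]), fm_path = unname(paths["fm"])
      )
    }
  }
  manifest <- do.call(rbind, rows)

  # calibration artifact: control points sampled from the true camera affine
  truth <- planar_transform(diag(opts$nir_scale, 2), opts$nir_offset)
  pts <- with_seed(rng_seed + 999L, cbind(
    stats::runif(130, 1, canvas_height_px),
    stats::runif(130, 1, canvas_width_px)
  ))
  nir_pts <- apply_transform(truth, pts)
  cp <- data.frame(rgb_row = pts[, 1], rgb_col = pts[, 2],
                   nir_row = nir_pts[, 1], nir_col = nir_pts[, 2])
  utils::write.csv(cp, file.path(out_dir, "registration_points.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
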