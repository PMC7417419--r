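#' Pipeline run configuration
#'
#' Builds the configuration object consumed by [segment_plant()],
#' [color_fractions()], [fluorescence_params()] and the water-budget
#' functions. Every tunable threshold of the pipeline lives here so a run is
#' fully described by one object (or one YAML file, see [read_config()]).
#'
#' Hue boundaries are on the 0--180 hue axis (degrees, truncated at 180):
#' bins 0--72 are the near-yellow (stressed-tissue) region and 73--180 the
#' near-green (healthy-tissue) region. The two windows must partition
#' 0--180 without overlap.
#'
#' @param hue_yellow integer vector of length 2, inclusive bin range of the
#'   near-yellow region. Default `c(0, 72)`.
#' @param hue_green integer vector of length 2, inclusive bin range of the
#'   near-green region. Default `c(73, 180)`.
#' @param seg_hue_window numeric length 2, hue window (degrees) a pixel must
#'   fall in to count as vegetation. Default `c(20, 180)` spans yellow
#'   through green foliage.
#' @param seg_sat_min,seg_val_min minimum HSV saturation / value for the hue
#'   rule (background pots and frames are grey: low saturation).
#' @param seg_exg_min minimum excess-green index `2G - R - B` (channels in
#'   `[0,1]`) for the alternative vegetation rule.
#' @param min_component_px connected components (8-connectivity) smaller
#'   than this are discarded from the mask. Default 50.
#' @param fluor_area_frac fluorescence area threshold as a fraction of
#'   `max(fm)`; pixels with `fm` above `fluor_area_frac * max(fm)` form the
#'   fluorescence area. Default 0.05.
#' @param registration_points number of control points used when sampling
#'   correspondences for RGB-to-NIR matching. Default 130.
#' @param daily_clock_hour hour of day (0--23) at which daily pot weights
#'   are sampled for loss-rate series. Default 11.
#' @param px_per_cm2 pixels per cm^2 used to convert projected area to leaf
#'   area when no direct leaf-area measurement is supplied. Rig-specific;
#'   default 100.
#'
#' @return A list of class `pheno_config`.
#' @seealso [read_config()]
#' @export
#' @examples
#' cfg <- pheno_config()
#' cfg$hue_yellow
pheno_config <- function(hue_yellow = c(0L, 72L),
                         hue_green = c(73L, 180L),
                         seg_hue_window = c(20, 180),
                         seg_sat_min = 0.25,
                         seg_val_min = 0.10,
                         seg_exg_min = 0.10,
                         min_component_px = 50L,
                         fluor_area_frac = 0.05,
                         registration_points = 130L,
                         daily_clock_hour = 11L,
                         px_per_cm2 = 100) {
  cfg <- list(
    hue_yellow = as.integer(hue_yellow),
    hue_green = as.integer(hue_green),
    seg_hue_window = as.numeric(seg_hue_window),
    seg_sat_min = seg_sat_min,
    seg_val_min = seg_val_min,
    seg_exg_min = seg_exg_min,
    min_component_px = as.integer(min_component_px),
    fluor_area_frac = fluor_area_frac,
    registration_points = as.integer(registration_points),
    daily_clock_hour = as.integer(daily_clock_hour),
    px_per_cm2 = px_per_cm2
  )
  class(cfg) <- "pheno_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pheno_config"))
  y <- cfg$hue_yellow
  g <- cfg$hue_green
  if (length(y) != 2L || length(g) != 2L) {
    stop("hue boundaries must each be a range of length 2", call. = FALSE)
  }
  # the two windows must tile [0, 180] exactly, no overlap, no gap
  if (y[1] != 0L || g[2] != 180L || g[1] != y[2] + 1L) {
    stop(sprintf(
      "hue regions [%d,%d] and [%d,%d] must partition [0,180] without overlap",
      y[1], y[2], g[1], g[2]
    ), call. = FALSE)
  }
  if (cfg$min_component_px < 1L) stop("min_component_px must be >= 1", call. = FALSE)
  if (cfg$fluor_area_frac <= 0 || cfg$fluor_area_frac >= 1) {
    stop("fluor_area_frac must be in (0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected rather than ignored, so a typo in a config file
#' fails loudly. Missing keys take their [pheno_config()] defaults.
#'
#' @param path path to a YAML file whose keys match [pheno_config()]
#'   arguments.
#' @return A `pheno_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pheno_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pheno_config, vals)
}

#' @export
print.pheno_config <- function(x, ...) {
  cat("<pheno_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-20s %s\n", k, paste(x[[k]], collapse = ", ")))
  }
  invisible(x)
}

# Minimal leveled logger used by the CLI and pipeline stages.
pheno_log <- function(level = c("INFO", "WARN", "ERROR"), stage, msg, key = NULL) {
  level <- match.arg(level)
  key_part <- if (is.null(key)) "" else paste0(" [", key, "]")
  message(sprintf("%s %s %s%s: %s", format(Sys.time(), "%H:%M:%S"),
                  level, stage, key_part, msg))
  invisible(NULL)
}
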