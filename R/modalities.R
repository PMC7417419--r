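# Modality metrics over the registered plant mask: NIR water-content index,
# mean canopy temperature, and dark-adapted chlorophyll fluorescence.

#' NIR water-content index
#'
#' Mean near-infrared reflectance (1450 nm water-absorption band) over the
#' plant mask, reported as its reciprocal: water absorbs at this band, so
#' well-hydrated tissue records LOW raw intensity and the reciprocal makes
#' the index increase with plant water content. The absolute scale depends
#' on sensor calibration; orderings and ratios are the meaningful output.
#'
#' @param nir numeric matrix in `[0,1]` (NIR frame).
#' @param mask logical mask in the NIR frame.
#' @return Numeric index (1 / mean reflectance).
#' @export
#' @examples
#' nir_intensity(matrix(0.5, 4, 4), matrix(TRUE, 4, 4)) # 2
nir_intensity <- function(nir, mask) {
  check_mask(mask)
  if (!all(dim(mask) == dim(nir))) {
    stop("mask and NIR raster dimensions differ", call. = FALSE)
  }
  m <- mean(nir[mask])
  if (m <= 0) stop("mean NIR reflectance is zero over the mask", call. = FALSE)
  1 / m
}

#' Mean plant temperature
#'
#' Arithmetic mean of the thermal raster (degrees Celsius per pixel) over
#' the plant mask. Stomatal closure under drought reduces evaporative
#' cooling, so stressed canopies run warmer.
#'
#' @param ir_c numeric matrix of temperatures in degrees Celsius.
#' @param mask logical mask in the IR frame.
#' @return Mean temperature in degrees Celsius.
#' @export
plant_temperature <- function(ir_c, mask) {
  check_mask(mask)
  if (!all(dim(mask) == dim(ir_c))) {
    stop("mask and IR raster dimensions differ", call. = FALSE)
  }
  mean(ir_c[mask])
}

#' Dark-adapted chlorophyll fluorescence parameters
#'
#' From a minimal-fluorescence frame `f0` and a saturating-pulse frame
#' `fm`, computes mean F0, Fm, Fv = Fm - F0 over the fluorescence area,
#' plus the Fm/F0 ratio and the maximum PSII quantum yield Fv/Fm. The
#' fluorescence area is the set of pixels whose `fm` exceeds
#' `cfg$fluor_area_frac * max(fm)` (the total area of plants that emitted
#' light); alternatively pass an explicit logical mask. Pixels with
#' `fm < f0` are physically impossible (a saturating pulse can only raise
#' fluorescence) and come from noise or misregistration; they are excluded
#' from the means and reported in `n_excluded_px`. Pixels with `fm == f0`
#' are kept: zero variable fluorescence is a valid (fully stressed)
#' reading, giving Fv = 0 and Fv/Fm = 0.
#'
#' @param f0_img,fm_img numeric matrices of equal size, relative units.
#' @param mask optional logical mask; if `NULL` the threshold rule defines
#'   the area.
#' @param cfg a [pheno_config()].
#' @return List of class `fluorescence_result`: `f0_mean`, `fm_mean`,
#'   `fv_mean`, `fm_over_f0`, `fv_over_fm`, `fluorescence_area_px`,
#'   `n_excluded_px`.
#' @export
#' @examples
#' f0 <- matrix(0.2, 5, 5); fm <- matrix(1, 5, 5)
#' fluorescence_params(f0, fm)$fv_over_fm # 0.8
fluorescence_params <- function(f0_img, fm_img, mask = NULL,
                                cfg = pheno_config()) {
  if (!all(dim(f0_img) == dim(fm_img))) {
    stop("F0 and Fm frames differ in size", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- fm_img > cfg$fluor_area_frac * max(fm_img)
  } else {
    check_mask(mask)
    if (!all(dim(mask) == dim(fm_img))) {
      stop("mask and fluorescence frames differ in size", call. = FALSE)
    }
  }
  area_px <- sum(mask)
  if (area_px == 0L) stop("empty fluorescence area", call. = FALSE)
  usable <- mask & (fm_img >= f0_img)
  n_excluded <- area_px - sum(usable)
  if (!any(usable)) stop("no pixels with Fm >= F0 in the fluorescence area",
                         call. = FALSE)
  f0_mean <- mean(f0_img[usable])
  fm_mean <- mean(fm_img[usable])
  fv_mean <- fm_mean - f0_mean
  structure(list(
    f0_mean = f0_mean,
    fm_mean = fm_mean,
    fv_mean = fv_mean,
    fm_over_f0 = fm_mean / f0_mean,
    fv_over_fm = fv_mean / fm_mean,
    fluorescence_area_px = area_px,
    n_excluded_px = n_excluded
  ), class = "fluorescence_result")
}

#' @export
print.fluorescence_result <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_result> area %d px | F0 %.3f Fm %.3f Fv %.3f | Fm/F0 %.2f Fv/Fm %.3f (%d px excluded)\n",
    x$fluorescence_area_px, x$f0_mean, x$fm_mean, x$fv_mean,
    x$fm_over_f0, x$fv_over_fm, x$n_excluded_px))
  invisible(x)
}
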