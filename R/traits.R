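# RGB trait extraction: the eight shape/color descriptors computed over the
# segmented plant mask, plus the hue histogram, color fractions and growth
# rate. All coordinates are 1-based (row, col); row index increases downward,
# so a drooping canopy raises center_of_mass_y.

check_mask <- function(mask, allow_empty = FALSE) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  if (!allow_empty && !any(mask)) stop("empty plant mask", call. = FALSE)
  invisible(mask)
}

mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE) # columns: row, col
}

#' Projected plant area
#'
#' The pixel count of the segmented shoot: the primary biomass proxy of
#' side- and top-view phenotyping.
#'
#' @param mask logical plant mask.
#' @return Integer pixel count.
#' @export
#' @examples
#' projected_plant_area(matrix(TRUE, 10, 10)) # 100
projected_plant_area <- function(mask) {
  check_mask(mask)
  sum(mask)
}

#' Object extent X and Y
#'
#' Width and height (pixels) of the axis-aligned bounding rectangle of the
#' mask: extent X measures plant width, extent Y the projected height.
#'
#' @param mask logical plant mask.
#' @return Named integer vector `c(x_px = , y_px = )`.
#' @export
object_extent <- function(mask) {
  check_mask(mask)
  rc <- mask_coords(mask)
  c(x_px = diff(range(rc[, "col"])) + 1L,
    y_px = diff(range(rc[, "row"])) + 1L)
}

#' Convex hull area of the plant mask
#'
#' Area of the convex hull of the four corner points of every foreground
#' pixel, computed with the monotone-chain algorithm and the shoelace
#' formula. Using pixel corners (not centers) makes solid convex masks
#' attain compactness exactly 1 and keeps the hull area at least the pixel
#' count. Collinear masks (a 1-pixel-wide line) degenerate to the thin
#' rectangle traced by their corners.
#'
#' @param mask logical plant mask.
#' @return Hull area in square pixels (numeric).
#' @export
convex_hull_area <- function(mask) {
  check_mask(mask)
  rc <- mask_coords(mask)
  pts <- pixel_corner_points(rc)
  hull <- convex_hull_chain(pts)
  polygon_area(hull)
}

# 4 corners of each pixel (centers at integer coords, pixels are unit squares)
pixel_corner_points <- function(rc) {
  r <- rc[, "row"]; cc <- rc[, "col"]
  pts <- cbind(
    x = c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5),
    y = c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  )
  unique(pts)
}

# Andrew's monotone chain; returns hull vertices in counter-clockwise order.
convex_hull_chain <- function(pts) {
  pts <- unique(pts)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    st <- integer(0)
    for (i in idx) {
      while (length(st) >= 2L &&
             cross(pts[st[length(st) - 1L], ], pts[st[length(st)], ], pts[i, ]) <= 0) {
        st <- st[-length(st)]
      }
      st <- c(st, i)
    }
    st
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull_idx <- c(lower[-length(lower)], upper[-length(upper)])
  pts[hull_idx, , drop = FALSE]
}

polygon_area <- function(v) {
  if (nrow(v) < 3L) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Compactness (solidity) of the plant mask
#'
#' Object area divided by convex hull area; the density of the canopy
#' including tillers and leaves. Always in `(0, 1]`, with solid convex
#' shapes attaining 1. (Conventionally this ratio is called solidity; the
#' phenotyping literature for shoot imaging calls it compactness, the name
#' kept here.)
#'
#' @param mask logical plant mask.
#' @return Numeric in `(0, 1]`.
#' @export
compactness <- function(mask) {
  projected_plant_area(mask) / convex_hull_area(mask)
}

#' Eccentricity of the plant mask
#'
#' Elongation of the equivalent ellipse from the second central moments of
#' the foreground pixel coordinates: `sqrt(1 - lambda2/lambda1)` with
#' `lambda1 >= lambda2` the covariance eigenvalues. 0 for a circle, 1 for a
#' line; single-pixel or perfectly isotropic masks return 0.
#'
#' @param mask logical plant mask.
#' @return Numeric in `[0, 1]`.
#' @export
eccentricity <- function(mask) {
  check_mask(mask)
  rc <- mask_coords(mask)
  n <- nrow(rc)
  if (n == 1L) return(0)
  r <- rc[, "row"]; cc <- rc[, "col"]
  mu20 <- sum((r - mean(r))^2) / n
  mu02 <- sum((cc - mean(cc))^2) / n
  mu11 <- sum((r - mean(r)) * (cc - mean(cc))) / n
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Center of mass Y
#'
#' Mean row index of the foreground pixels. Rows grow downward, so leaf
#' drying and drooping increase this value.
#'
#' @param mask logical plant mask.
#' @return Numeric row coordinate.
#' @export
center_of_mass_y <- function(mask) {
  check_mask(mask)
  mean(mask_coords(mask)[, "row"])
}

#' Perimeter of the plant mask
#'
#' Total boundary length of all components by the marching-squares contour
#' at level 0.5 between pixel centers; interior holes are filled first so
#' only outside boundaries count. Under this convention a solid `n x n`
#' square measures `4(n-1) + 2*sqrt(2)` (straight sides plus four diagonal
#' corner cuts) and a single pixel `2*sqrt(2)`.
#'
#' @param mask logical plant mask.
#' @return Numeric contour length in pixels.
#' @export
perimeter <- function(mask) {
  check_mask(mask)
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  m <- matrix(FALSE, nrow(filled) + 2L, ncol(filled) + 2L)
  m[2:(nrow(filled) + 1L), 2:(ncol(filled) + 1L)] <- filled
  h <- nrow(m); w <- ncol(m)
  a <- m[-h, -w]; b <- m[-h, -1]; cc <- m[-1, -w]; d <- m[-1, -1]
  idx <- a + 2L * b + 4L * cc + 8L * d
  s <- sqrt(2) / 2
  seg_len <- c(0, s, s, 1, s, 1, sqrt(2), s, s, sqrt(2), 1, s, 1, s, s, 0)
  sum(seg_len[idx + 1L])
}

#' Hue histogram over the plant mask
#'
#' Per-pixel HSV hue of the plant pixels on the 0--180 hue axis (degrees;
#' foliage hues never exceed ~180 degrees, rare purples collapse into the
#' top bin), binned into 181 integer bins. Bin counts always sum to the
#' projected plant area.
#'
#' @param rgb numeric `H x W x 3` array in `[0,1]`.
#' @param mask logical plant mask of matching size.
#' @return Integer vector of length 181 named `"0"`..`"180"`, class
#'   `hue_histogram`.
#' @export
hue_histogram <- function(rgb, mask) {
  check_mask(mask)
  if (!all(dim(mask) == dim(rgb)[1:2])) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  r <- rgb[, , 1][mask]; g <- rgb[, , 2][mask]; b <- rgb[, , 3][mask]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  bins <- pmin(180L, as.integer(floor(hsv[1, ] * 360)))
  counts <- tabulate(bins + 1L, nbins = 181L)
  names(counts) <- 0:180
  class(counts) <- "hue_histogram"
  counts
}

#' Near-green / near-yellow color fractions
#'
#' Splits a [hue_histogram()] at the configured boundary: bins 0--72
#' (near-yellow) hold stressed, discolored tissue; bins 73--180
#' (near-green) healthy tissue. Fractions sum to 1 over plant pixels.
#'
#' @param hist a [hue_histogram()] (or any length-181 count vector).
#' @param cfg a [pheno_config()] carrying the boundary bins.
#' @return Named numeric `c(green_fraction = , yellow_fraction = )`.
#' @export
color_fractions <- function(hist, cfg = pheno_config()) {
  counts <- as.numeric(hist)
  if (length(counts) != 181L) stop("expected 181 hue bins", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("empty hue histogram", call. = FALSE)
  y <- cfg$hue_yellow; g <- cfg$hue_green
  yellow <- sum(counts[(y[1]:y[2]) + 1L]) / total
  green <- sum(counts[(g[1]:g[2]) + 1L]) / total
  c(green_fraction = green, yellow_fraction = yellow)
}

#' Growth rate from a projected-area series
#'
#' Pixel-area difference between two days divided by the elapsed days; the
#' daily canopy expansion (negative while wilting).
#'
#' @param area_series data frame with columns `day` and `area_px` (or a
#'   2-column matrix in that order).
#' @param d1,d2 the two days to compare, `d1 < d2`, both present in the
#'   series.
#' @return Numeric growth rate in pixels/day.
#' @export
#' @examples
#' growth_rate(data.frame(day = c(4, 6), area_px = c(10000, 14000)), 4, 6)
growth_rate <- function(area_series, d1, d2) {
  area_series <- as.data.frame(area_series)
  if (!all(c("day", "area_px") %in% names(area_series))) {
    names(area_series)[1:2] <- c("day", "area_px")
  }
  if (d1 >= d2) stop("d1 must be earlier than d2", call. = FALSE)
  a1 <- area_series$area_px[match(d1, area_series$day)]
  a2 <- area_series$area_px[match(d2, area_series$day)]
  if (is.na(a1) || is.na(a2)) {
    stop("day ", if (is.na(a1)) d1 else d2, " not present in area series",
         call. = FALSE)
  }
  (a2 - a1) / (d2 - d1)
}

#' All RGB shape and color traits for one mask
#'
#' Convenience wrapper returning one trait-table row fragment: projected
#' area, extents, hull area, compactness, eccentricity, center of mass Y,
#' perimeter, and the two hue fractions.
#'
#' @param rgb numeric `H x W x 3` array in `[0,1]`.
#' @param mask logical plant mask.
#' @param cfg a [pheno_config()].
#' @return A one-row data frame.
#' @export
rgb_trait_record <- function(rgb, mask, cfg = pheno_config()) {
  ext <- object_extent(mask)
  frac <- color_fractions(hue_histogram(rgb, mask), cfg)
  data.frame(
    projected_area_px = projected_plant_area(mask),
    object_extent_x_px = unname(ext["x_px"]),
    object_extent_y_px = unname(ext["y_px"]),
    convex_hull_area_px = convex_hull_area(mask),
    compactness = compactness(mask),
    eccentricity = eccentricity(mask),
    center_of_mass_y_px = center_of_mass_y(mask),
    perimeter_px = perimeter(mask),
    green_fraction = unname(frac["green_fraction"]),
    yellow_fraction = unname(frac["yellow_fraction"])
  )
}
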