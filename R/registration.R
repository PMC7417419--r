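# RGB-to-NIR registration: the two cameras differ in resolution and
# position, so the plant mask found in the RGB frame is carried into the
# NIR/IR/fluorescence frame by an affine transform fitted to control-point
# correspondences.

#' Paired control points between the RGB and NIR frames
#'
#' @param rgb_points,nir_points numeric `n x 2` matrices of (row, col)
#'   coordinates, one row per correspondence, `n >= 3`.
#' @return Object of class `control_points`.
#' @export
control_points <- function(rgb_points, nir_points) {
  rgb_points <- as.matrix(rgb_points); nir_points <- as.matrix(nir_points)
  if (ncol(rgb_points) != 2L || ncol(nir_points) != 2L) {
    stop("control points must be n x 2 (row, col) matrices", call. = FALSE)
  }
  if (nrow(rgb_points) != nrow(nir_points)) {
    stop("point sets differ in length", call. = FALSE)
  }
  if (nrow(rgb_points) < 3L) {
    stop("at least 3 control-point pairs are required for an affine fit",
         call. = FALSE)
  }
  if (anyDuplicated(rgb_points)) {
    stop("duplicate RGB control points", call. = FALSE)
  }
  structure(list(rgb = rgb_points, nir = nir_points), class = "control_points")
}

#' Planar affine transform between camera frames
#'
#' Maps RGB (row, col) coordinates to NIR (row, col): `nir = A %*% rgb + b`.
#'
#' @param A 2x2 numeric matrix.
#' @param b numeric length-2 offset.
#' @param rms_residual_px root-mean-square control-point residual (pixels).
#' @return Object of class `planar_transform`.
#' @export
planar_transform <- function(A, b, rms_residual_px = 0) {
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  if (!all(is.finite(A)) || !all(is.finite(b)) || length(b) != 2L) {
    stop("non-finite affine coefficients", call. = FALSE)
  }
  if (rms_residual_px < 0) stop("negative rms residual", call. = FALSE)
  structure(list(A = A, b = b, rms_residual_px = rms_residual_px),
            class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat("<planar_transform> nir = A rgb + b, rms residual",
      format(x$rms_residual_px, digits = 4), "px\n")
  cat("A =\n"); print(x$A)
  cat("b =", x$b, "\n")
  invisible(x)
}

#' Fit an affine RGB-to-NIR transform from control points
#'
#' Ordinary least squares on the NIR-frame residuals: each output
#' coordinate is a linear function of (rgb_row, rgb_col, 1). Requires at
#' least 3 non-collinear pairs (6 degrees of freedom); exact
#' correspondences are recovered to machine precision with zero residual.
#'
#' @param points a [control_points()] set.
#' @return A [planar_transform()] with its RMS residual.
#' @export
#' @examples
#' rgbp <- cbind(c(1, 1, 100, 100), c(1, 200, 1, 200))
#' nirp <- 0.25 * rgbp + matrix(c(10, 20), 4, 2, byrow = TRUE)
#' fit_transform(control_points(rgbp, nirp))
fit_transform <- function(points) {
  stopifnot(inherits(points, "control_points"))
  X <- cbind(points$rgb, 1)
  if (qr(X)$rank < 3L) {
    stop("control points are collinear; affine transform not identifiable",
         call. = FALSE)
  }
  coefs <- qr.solve(X, points$nir) # 3 x 2, columns: nir_row, nir_col
  A <- t(coefs[1:2, ])
  b <- coefs[3, ]
  pred <- X %*% coefs
  rms <- sqrt(mean((pred - points$nir)^2))
  planar_transform(A, b, rms)
}

#' Apply a planar transform to (row, col) coordinates
#'
#' @param t a [planar_transform()].
#' @param coords numeric `n x 2` matrix of (row, col) points.
#' @return Numeric `n x 2` matrix of transformed points.
#' @export
apply_transform <- function(t, coords) {
  stopifnot(inherits(t, "planar_transform"))
  coords <- matrix(as.numeric(coords), ncol = 2)
  sweep(coords %*% t(t$A), 2, t$b, `+`)
}

invert_transform <- function(t) {
  Ainv <- solve(t$A)
  planar_transform(Ainv, -Ainv %*% t$b, t$rms_residual_px)
}

#' Transfer the RGB plant mask into the NIR frame
#'
#' Nearest-neighbor warp: every NIR pixel is mapped back through the
#' inverse transform and takes the mask value of the nearest RGB pixel.
#' Nearest-neighbor sampling keeps the mask binary.
#'
#' @param mask logical RGB-frame plant mask.
#' @param t a [planar_transform()] (RGB to NIR).
#' @param nir_shape integer `c(rows, cols)` of the NIR frame.
#' @return Logical matrix of size `nir_shape`. Errors if the warped mask
#'   lands entirely outside the frame.
#' @export
transfer_mask <- function(mask, t, nir_shape) {
  check_mask(mask)
  nir_shape <- as.integer(nir_shape)
  grid <- cbind(
    rep(seq_len(nir_shape[1]), times = nir_shape[2]),
    rep(seq_len(nir_shape[2]), each = nir_shape[1])
  )
  src <- apply_transform(invert_transform(t), grid)
  sr <- as.integer(round(src[, 1])); sc <- as.integer(round(src[, 2]))
  ok <- sr >= 1L & sr <= nrow(mask) & sc >= 1L & sc <= ncol(mask)
  vals <- logical(nrow(grid))
  vals[ok] <- mask[cbind(sr[ok], sc[ok])]
  out <- matrix(vals, nir_shape[1], nir_shape[2])
  if (!any(out)) stop("mask falls outside the NIR frame", call. = FALSE)
  out
}
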