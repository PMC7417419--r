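#' Segment the plant from an RGB image
#'
#' Foreground pixels pass a vegetation color rule: HSV hue inside
#' `cfg$seg_hue_window` (with saturation and value floors) OR excess-green
#' index `2G - R - B` above `cfg$seg_exg_min`. The rule image is then
#' regularized by a 3x3 morphological opening and closing, and connected
#' components (8-connectivity) smaller than `cfg$min_component_px` pixels
#' are discarded. Deterministic: the same image and config always give the
#' same mask.
#'
#' @param rgb numeric `H x W x 3` array in `[0,1]`.
#' @param cfg a [pheno_config()].
#' @param image_key optional identifier included in error messages.
#' @return Logical `H x W` matrix (the plant mask) with at least one `TRUE`
#'   pixel.
#' @export
#' @examples
#' scene <- render_scene(plant_spec(rng_seed = 1))
#' mask <- segment_plant(scene$rgb, pheno_config())
#' sum(mask)
segment_plant <- function(rgb, cfg = pheno_config(), image_key = NULL) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L) {
    stop("segment_plant expects an H x W x 3 RGB array", call. = FALSE)
  }
  if (any(dim(rgb)[1:2] == 0L)) stop("empty image", call. = FALSE)
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  hsv <- rgb_to_hsv_deg(r, g, b)
  hue_rule <- hsv$h >= cfg$seg_hue_window[1] & hsv$h <= cfg$seg_hue_window[2] &
    hsv$s >= cfg$seg_sat_min & hsv$v >= cfg$seg_val_min
  exg_rule <- (2 * g - r - b) > cfg$seg_exg_min
  fg <- hue_rule | exg_rule

  fg_img <- EBImage::Image(fg * 1)
  brush <- EBImage::makeBrush(3L, shape = "diamond")
  fg_img <- EBImage::closing(EBImage::opening(fg_img, brush), brush)
  fg <- EBImage::imageData(fg_img) > 0.5

  mask <- clean_mask(fg, cfg$min_component_px)
  if (!any(mask)) {
    key_part <- if (is.null(image_key)) "" else paste0(" [", image_key, "]")
    stop("no plant detected", key_part, call. = FALSE)
  }
  mask
}

#' Remove small connected components from a mask
#'
#' Components are 8-connected (diagonally touching pixels belong together,
#' which keeps thin diagonal leaf segments intact). Never adds pixels;
#' raising the threshold can only shrink the mask.
#'
#' @param mask logical matrix.
#' @param min_component_px minimum component size to keep (pixels).
#' @return Logical matrix of the same shape; may be all-`FALSE`.
#' @export
clean_mask <- function(mask, min_component_px = 50L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) return(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_px)
  out <- mask & (lab %in% keep) # lab 0 never matches
  dim(out) <- dim(mask)
  out
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a small union-find.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbor label pairs (down-right and down-left shifts)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # (r,c) vs (r+1,c+1)
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # (r,c+1) vs (r+1,c)
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

# Vectorized RGB -> HSV with hue in degrees [0, 360).
rgb_to_hsv_deg <- function(r, g, b) {
  dm <- dim(r)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 1)
  h <- hsv[1, ] * 360
  s <- hsv[2, ]
  v <- hsv[3, ]
  dim(h) <- dm; dim(s) <- dm; dim(v) <- dm
  list(h = h, s = s, v = v)
}

#' Write / read a plant mask as PNG
#'
#' Masks persist as single-channel PNGs (0 = background, 1 = plant).
#'
#' @param mask logical matrix.
#' @param path PNG path.
#' @return `path` (writer, invisibly) or a logical matrix (reader).
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}
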