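#' Read a raster image (PNG or TIFF)
#'
#' PNG rasters are returned as numeric arrays in `[0,1]` (`H x W` or
#' `H x W x 3`). Float TIFFs (NIR / IR / fluorescence frames) are returned
#' as numeric matrices; a physical scale written by [write_raster()] is
#' re-applied so e.g. temperature rasters come back in degrees Celsius.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param scale numeric; stored values are multiplied by `scale` after
#'   reading. Use the same value the raster was written with (TIFF storage
#'   is confined to `[0,1]`, so out-of-range physical units ride on this
#'   factor). Default 1.
#' @return Numeric array, rows indexing image rows (row 1 at the top).
#' @export
read_raster <- function(path, scale = 1) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '.", ext, "' (PNG/TIFF only): ", path,
         call. = FALSE)
  )
  if (scale != 1) img <- img * scale
  img
}

#' Write a raster image (PNG or TIFF)
#'
#' 8-bit RGB goes to PNG; single-channel float data goes to 32-bit float
#' TIFF. TIFF float storage only covers `[0,1]`, so rasters in physical
#' units (e.g. degrees Celsius) are divided by `scale` on disk; pass the
#' same `scale` to [read_raster()] to recover the units. Values are checked,
#' not silently clipped.
#'
#' @param raster numeric array (`H x W` or `H x W x 3`).
#' @param path output path; extension selects the format.
#' @param scale divisor applied before writing a TIFF (default 1).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (min(raster) < 0 || max(raster) > 1) {
      stop("PNG rasters must be in [0,1]", call. = FALSE)
    }
    png::writePNG(raster, path)
  } else if (ext %in% c("tif", "tiff")) {
    stored <- raster / scale
    if (min(stored) < 0 || max(stored) > 1) {
      stop("TIFF storage covers [0,1]; choose a scale covering the data range",
           call. = FALSE)
    }
    tiff::writeTIFF(stored, path, bits.per.sample = 32L, compression = "none")
  } else {
    stop("unsupported raster format '.", ext, "' (PNG/TIFF only)", call. = FALSE)
  }
  invisible(path)
}

#' Construct a pot-weighing series
#'
#' @param time `POSIXct` vector, strictly increasing.
#' @param weight_g numeric recorded pot weights (grams), all positive.
#' @param events data frame with columns `time` (POSIXct) and `added_g`
#'   (grams added by an irrigation refill); may have zero rows.
#' @param pot_kind `"planted"` or `"empty"` (soil-only reference pot).
#' @return Object of class `weighing_series`.
#' @export
weighing_series <- function(time, weight_g,
                            events = data.frame(time = as.POSIXct(character(), tz = "UTC"),
                                                added_g = numeric()),
                            pot_kind = c("planted", "empty")) {
  pot_kind <- match.arg(pot_kind)
  if (length(time) != length(weight_g)) {
    stop("time and weight_g lengths differ", call. = FALSE)
  }
  if (length(time) == 0L) stop("empty weighing series", call. = FALSE)
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) {
    bad <- which(dt <= 0) + 1L
    stop("timestamps not strictly increasing at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(weight_g <= 0)) stop("weights must be positive", call. = FALSE)
  if (nrow(events)) {
    if (any(events$time < time[1]) || any(events$time > time[length(time)])) {
      stop("irrigation events outside series time range", call. = FALSE)
    }
  }
  structure(list(time = time, weight_g = weight_g, events = events,
                 pot_kind = pot_kind),
            class = "weighing_series")
}

#' @export
print.weighing_series <- function(x, ...) {
  cat(sprintf("<weighing_series> %s pot, %d samples, %s .. %s, %d irrigation event(s)\n",
              x$pot_kind, length(x$time),
              format(x$time[1]), format(x$time[length(x$time)]),
              nrow(x$events)))
  invisible(x)
}

#' Read a pot-weighing CSV
#'
#' Expected columns: `time` (ISO-8601, UTC), `weight_g`, and optionally
#' `irrigation_added_g` (0 except on refill rows). Malformed input is
#' rejected with the offending rows listed, never coerced.
#'
#' @param path CSV path.
#' @param pot_kind `"planted"` or `"empty"`.
#' @return A [weighing_series()].
#' @export
read_weighing_csv <- function(path, pot_kind = c("planted", "empty")) {
  pot_kind <- match.arg(pot_kind)
  if (!file.exists(path)) stop("weighing CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "weight_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("weighing CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tm <- as.POSIXct(df$time, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(tm)) {
    stop("unparseable timestamps at rows: ",
         paste(utils::head(which(is.na(tm)), 5L), collapse = ", "), call. = FALSE)
  }
  ev <- data.frame(time = as.POSIXct(character(), tz = "UTC"), added_g = numeric())
  if ("irrigation_added_g" %in% names(df)) {
    hit <- which(df$irrigation_added_g > 0)
    ev <- data.frame(time = tm[hit], added_g = df$irrigation_added_g[hit])
  }
  weighing_series(tm, as.numeric(df$weight_g), ev, pot_kind)
}

#' Write a weighing series to CSV
#'
#' Inverse of [read_weighing_csv()]: one row per sample, ISO-8601 UTC
#' timestamps, refill masses on the rows where they occurred.
#'
#' @param series a [weighing_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weighing_csv <- function(series, path) {
  stopifnot(inherits(series, "weighing_series"))
  added <- numeric(length(series$time))
  if (nrow(series$events)) {
    idx <- match(as.numeric(series$events$time), as.numeric(series$time))
    if (anyNA(idx)) stop("event timestamps not on the sampling grid", call. = FALSE)
    added[idx] <- series$events$added_g
  }
  df <- data.frame(
    time = format(series$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    weight_g = series$weight_g,
    irrigation_added_g = added
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a trait table
#'
#' The trait table holds one row per `(plant_id, day, view)` with the RGB
#' shape descriptors, color fractions and modality metrics. Keys must be
#' present and unique.
#'
#' @param table data frame with at least `plant_id`, `day`, `view` columns.
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the validated data frame (reader).
#' @export
write_trait_table <- function(table, path) {
  validate_trait_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(df)
  df
}

validate_trait_table <- function(table) {
  need <- c("plant_id", "day", "view")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("trait table missing key columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(table$plant_id) || anyNA(table$day) || anyNA(table$view)) {
    stop("trait table keys contain missing values", call. = FALSE)
  }
  key <- paste(table$plant_id, table$day, table$view, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (plant_id, day, view) keys in trait table", call. = FALSE)
  }
  invisible(table)
}
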