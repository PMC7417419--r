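# Cohort-level aggregation: extraction of the full trait table from a
# rendered (or otherwise stored) image cohort, trait-trait Pearson
# correlations and group summaries.

#' Extract the full trait table from a cohort directory
#'
#' Runs the whole pipeline for every row of a cohort manifest (as written
#' by [generate_cohort()]): segment the RGB image, compute the shape and
#' color traits, fit the RGB-to-NIR transform from the control-point file,
#' transfer the mask, and append the NIR water index, mean plant
#' temperature and fluorescence parameters.
#'
#' @param cohort_dir directory containing `manifest.csv`,
#'   `registration_points.csv` and the rasters.
#' @param cfg a [pheno_config()].
#' @param view view label recorded in the table (side-view angle 0, 120,
#'   240 or `"top"`). Default `"0"`.
#' @param verbose emit per-plant progress log lines.
#' @return A trait table data frame, one row per (plant_id, day, view).
#' @export
extract_cohort <- function(cohort_dir, cfg = pheno_config(), view = "0",
                           verbose = FALSE) {
  manifest_path <- file.path(cohort_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", cohort_dir, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  cp_path <- file.path(cohort_dir, "registration_points.csv")
  transform <- NULL
  if (file.exists(cp_path)) {
    cp <- utils::read.csv(cp_path)
    transform <- fit_transform(control_points(
      cbind(cp$rgb_row, cp$rgb_col), cbind(cp$nir_row, cp$nir_col)))
  }
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    key <- sprintf("%s d%d", m$plant_id, m$day)
    if (verbose) pheno_log("INFO", "extract", "segmenting", key)
    rgb <- read_raster(file.path(cohort_dir, m$rgb_path))
    mask <- segment_plant(rgb, cfg, image_key = key)
    rec <- rgb_trait_record(rgb, mask, cfg)
    rec <- cbind(data.frame(plant_id = m$plant_id, day = m$day, view = view,
                            genotype = m$genotype, group = m$group), rec)

    if (!is.null(transform) && !is.na(m$nir_path)) {
      nir <- read_raster(file.path(cohort_dir, m$nir_path))
      mask_nir <- transfer_mask(mask, transform, dim(nir))
      rec$nir_intensity <- nir_intensity(nir, mask_nir)
      rec$area_nir_px <- sum(mask_nir)
      if (!is.na(m$ir_path)) {
        ir <- read_raster(file.path(cohort_dir, m$ir_path), scale = 100)
        rec$plant_temperature_c <- plant_temperature(ir, mask_nir)
      }
      if (!is.na(m$f0_path) && !is.na(m$fm_path)) {
        f0 <- read_raster(file.path(cohort_dir, m$f0_path))
        fm <- read_raster(file.path(cohort_dir, m$fm_path))
        fl <- fluorescence_params(f0, fm, cfg = cfg)
        rec$f0_mean <- fl$f0_mean
        rec$fm_mean <- fl$fm_mean
        rec$fv_mean <- fl$fv_mean
        rec$fm_over_f0 <- fl$fm_over_f0
        rec$fv_over_fm <- fl$fv_over_fm
        rec$fluorescence_area_px <- fl$fluorescence_area_px
      }
    }
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  validate_trait_table(out)
  out
}

#' Pairwise Pearson correlations between traits
#'
#' Complete-case Pearson correlation matrix over the selected trait
#' columns. Constant columns make the coefficient undefined; those cells
#' are returned as `NA` and the trait names flagged, never silently set
#' to 0.
#'
#' @param table a trait table data frame.
#' @param traits character vector of numeric column names (>= 2).
#' @return Object of class `correlation_matrix`: list with `r` (symmetric
#'   matrix, unit diagonal), `n` (complete cases used), `flagged`
#'   (constant traits), `dropped_rows` (incomplete rows discarded).
#' @export
#' @examples
#' tab <- data.frame(a = 1:10, b = 2 * (1:10), c = rnorm(10))
#' pearson_matrix(tab, c("a", "b", "c"))$r
pearson_matrix <- function(table, traits) {
  if (length(traits) < 2L) stop("need at least two traits", call. = FALSE)
  miss <- setdiff(traits, names(table))
  if (length(miss)) {
    stop("traits not in table: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(table[, traits, drop = FALSE])
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 3L) stop("fewer than 3 complete rows", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  flagged <- traits[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  if (length(flagged)) {
    warning("constant trait(s), correlations undefined: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  structure(list(r = r, n = nrow(x), flagged = flagged,
                 dropped_rows = dropped),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d traits, n = %d complete rows\n",
              ncol(x$r), x$n))
  print(round(x$r, 3))
  if (length(x$flagged)) cat("flagged constant:", x$flagged, "\n")
  invisible(x)
}

#' Per-group mean and standard deviation of traits
#'
#' @param table a trait table data frame.
#' @param group_keys character vector of grouping columns.
#' @param value_cols numeric columns to summarize; defaults to every
#'   numeric non-key column.
#' @return Long data frame: group keys, `trait`, `mean`, `sd` (`NA` for
#'   singleton groups), `n`.
#' @export
group_summary <- function(table, group_keys, value_cols = NULL) {
  miss <- setdiff(group_keys, names(table))
  if (length(miss)) {
    stop("group keys not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(value_cols)) {
    numeric_cols <- names(table)[vapply(table, is.numeric, logical(1))]
    value_cols <- setdiff(numeric_cols, group_keys)
  }
  if (!length(value_cols)) stop("no numeric columns to summarize", call. = FALSE)
  key <- interaction(table[group_keys], drop = TRUE, sep = "|")
  out <- list()
  for (v in value_cols) {
    agg_mean <- tapply(table[[v]], key, mean)
    agg_sd <- tapply(table[[v]], key, function(z) {
      if (length(z) < 2L) NA_real_ else stats::sd(z)
    })
    agg_n <- tapply(table[[v]], key, length)
    keys_df <- do.call(rbind, strsplit(names(agg_mean), "|", fixed = TRUE))
    keys_df <- as.data.frame(keys_df, stringsAsFactors = FALSE)
    names(keys_df) <- group_keys
    out[[v]] <- cbind(keys_df, data.frame(
      trait = v, mean = as.numeric(agg_mean), sd = as.numeric(agg_sd),
      n = as.integer(agg_n)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
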