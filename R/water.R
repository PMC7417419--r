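# Gravimetric water budget: water-use efficiency, daily loss rates, plant
# water loss rate (PWLR), transpiration rate (TR) and irrigation summaries
# from pot-weighing series.

#' Water-use efficiency
#'
#' Dry-mass gain over a drought interval divided by the total water
#' irrigated in that interval:
#' `WUE = (dry_after - dry_before) / total_irrigated` (g dry mass per g
#' water). May be zero or negative if mass was lost.
#'
#' @param dry_before_g,dry_after_g shoot dry weights (g) before and after
#'   the interval.
#' @param total_irrigated_g total irrigation water over the interval (g),
#'   strictly positive.
#' @return Numeric WUE.
#' @export
#' @examples
#' water_use_efficiency(1.0, 1.5, 500) # 1e-3
water_use_efficiency <- function(dry_before_g, dry_after_g, total_irrigated_g) {
  if (total_irrigated_g <= 0) {
    stop("total irrigated water must be positive", call. = FALSE)
  }
  (dry_after_g - dry_before_g) / total_irrigated_g
}

#' Daily water-loss rate from a weighing series
#'
#' The day-0 pot weight counts as 100%; the rate for day d is
#' `100 * (W(d-1) - W(d)) / W(0)` with weights sampled at a fixed daily
#' clock time (default 11:00, the usual mid-morning reading). The series
#' must be free of irrigation events inside the analysed window ("none
#' mode"); series with refills need event-aware correction first.
#'
#' @param series a [weighing_series()].
#' @param clock_hour hour of day at which the daily weight is sampled.
#' @return Numeric vector of per-day loss rates (percent/day), named by day
#'   index `1..D`, with attribute `w0` (the day-0 base weight in g).
#' @export
daily_water_loss_rate <- function(series, clock_hour = 11L) {
  stopifnot(inherits(series, "weighing_series"))
  if (nrow(series$events) > 0L) {
    stop("irrigation events inside the analysis window; ",
         "apply event-aware correction before computing loss rates",
         call. = FALSE)
  }
  lt <- as.POSIXlt(series$time, tz = "UTC")
  at_clock <- which(lt$hour == clock_hour & lt$min == 0L & lt$sec == 0)
  if (length(at_clock) < 2L) {
    stop("need at least two days sampled at the ", clock_hour, ":00 clock time",
         call. = FALSE)
  }
  w <- series$weight_g[at_clock]
  w0 <- w[1]
  rates <- 100 * (w[-length(w)] - w[-1]) / w0
  names(rates) <- seq_along(rates)
  attr(rates, "w0") <- w0
  rates
}

#' Plant water-loss rate (PWLR)
#'
#' Elementwise difference between the daily loss rate of planted pots and
#' that of plant-free (soil-only) pots: the share of pot-weight loss
#' attributable to transpiration. Late in severe drought the planted rate
#' can drop below the soil rate; negative values are kept (and flagged via
#' a warning), not clipped.
#'
#' @param planted_rates,empty_pot_rates numeric per-day rate vectors of
#'   equal length (percent/day).
#' @return Numeric per-day PWLR series (percent/day).
#' @export
#' @examples
#' pwlr(7.6, 2.4) # 5.2
pwlr <- function(planted_rates, empty_pot_rates) {
  if (length(planted_rates) != length(empty_pot_rates)) {
    stop("rate series differ in length", call. = FALSE)
  }
  out <- as.numeric(planted_rates) - as.numeric(empty_pot_rates)
  names(out) <- names(planted_rates)
  if (any(out < 0)) {
    warning("negative PWLR on day(s) ",
            paste(which(out < 0), collapse = ", "),
            " (transpiration below soil evaporation; typical of late drought)",
            call. = FALSE)
  }
  out
}

#' Transpiration rate (TR)
#'
#' PWLR normalized by leaf area: `TR = PWLR / leaf_area_cm2`, in percent
#' per cm^2 per day.
#'
#' @param pwlr_series numeric per-day PWLR series (percent/day).
#' @param leaf_area_cm2 leaf area in cm^2, strictly positive.
#' @return Numeric per-day TR series.
#' @export
transpiration_rate <- function(pwlr_series, leaf_area_cm2) {
  if (leaf_area_cm2 <= 0) stop("leaf area must be positive", call. = FALSE)
  as.numeric(pwlr_series) / leaf_area_cm2
}

#' Irrigation summary of a weighing series
#'
#' @param series a [weighing_series()] recorded in deviation mode.
#' @return Named numeric `c(count = , total_added_g = )`; `(0, 0)` when no
#'   refills occurred.
#' @export
irrigation_summary <- function(series) {
  stopifnot(inherits(series, "weighing_series"))
  c(count = nrow(series$events),
    total_added_g = sum(series$events$added_g))
}

#' Percent difference between two group means
#'
#' `100 * (a - b) / a`, with `a` the reference (larger-magnitude) mean, the
#' form used for worked comparisons between genotype groups.
#'
#' @param a reference mean (nonzero).
#' @param b comparison mean.
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(643, 549) # ~14.6
percent_difference <- function(a, b) {
  if (a == 0) stop("reference value is zero", call. = FALSE)
  100 * (a - b) / a
}

#' Fold change between two group means
#'
#' @param a numerator mean.
#' @param b denominator mean (nonzero).
#' @return `a / b`.
#' @export
#' @examples
#' fold_change(7.0e4, 2.4e4) # ~2.9
fold_change <- function(a, b) {
  if (b == 0) stop("denominator is zero", call. = FALSE)
  a / b
}

#' Full water budget for a planted/empty pot pair
#'
#' Convenience wrapper combining the elementary operations: daily loss
#' rates for both pots, PWLR, TR, WUE and the irrigation summary.
#'
#' @param planted a planted-pot [weighing_series()] without refills in the
#'   analysis window.
#' @param empty a soil-only [weighing_series()].
#' @param leaf_area_cm2 leaf area (cm^2).
#' @param dry_before_g,dry_after_g,total_irrigated_g optional WUE inputs;
#'   WUE is `NA` when omitted.
#' @param clock_hour daily sampling hour.
#' @return List of class `water_budget_result` with elements `wue`,
#'   `total_water_loss_rate_pct`, `soil_water_loss_rate_pct`, `pwlr_pct`,
#'   `tr_pct_per_cm2`, `irrigation`.
#' @export
water_budget <- function(planted, empty, leaf_area_cm2,
                         dry_before_g = NA, dry_after_g = NA,
                         total_irrigated_g = NA, clock_hour = 11L) {
  total <- daily_water_loss_rate(planted, clock_hour)
  soil <- daily_water_loss_rate(empty, clock_hour)
  d <- min(length(total), length(soil))
  p <- pwlr(total[seq_len(d)], soil[seq_len(d)])
  wue <- if (is.na(total_irrigated_g)) NA_real_ else {
    water_use_efficiency(dry_before_g, dry_after_g, total_irrigated_g)
  }
  structure(list(
    wue = wue,
    total_water_loss_rate_pct = total[seq_len(d)],
    soil_water_loss_rate_pct = soil[seq_len(d)],
    pwlr_pct = p,
    tr_pct_per_cm2 = transpiration_rate(p, leaf_area_cm2),
    irrigation = irrigation_summary(planted)
  ), class = "water_budget_result")
}
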