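#' Label true-positive SVA half hours in a filtered series
#'
#' A half hour is a detected adsorption event when its latent heat flux is
#' negative (toward the ground) and the fitted template says adsorption is
#' physically possible there (soil moisture strictly below the boundary at
#' the prevailing atmospheric humidity). All quality-filtered records are
#' eligible — by default the full 24 h, not only nighttime — since the event
#' census uses individual records rather than binned dominance. The null
#' template labels nothing.
#'
#' @param series A [site_series()] after [apply_filters()].
#' @param template An [evea_template()], typically `fit_site(...)$best_template`.
#' @param night_only Restrict labeling to nighttime records.
#' @return Logical vector aligned to `series$records` (FALSE for invalid
#'   records).
#' @export
label_tp <- function(series, template, night_only = FALSE) {
  stopifnot(inherits(series, "site_series"), inherits(template, "evea_template"))
  r <- series$records
  if (!"valid" %in% names(r)) stop("run apply_filters() before label_tp()")
  ok <- r$valid & !is.na(r$le) & !is.na(r$rha) & !is.na(r$vwc)
  if (night_only) ok <- ok & !is.na(r$night) & r$night
  lab <- rep(FALSE, nrow(r))
  if (any(ok)) {
    lab[ok] <- r$le[ok] < 0 & is_sva_possible(template, r$rha[ok], r$vwc[ok])
  }
  lab
}

#' Aggregate labeled half hours to daily SVA statistics
#'
#' @param labels Logical vector from [label_tp()].
#' @param series The matching [site_series()].
#' @param day_threshold_h Minimum SVA duration for a day to count as an SVA
#'   day, hours.
#' @return Data frame with one row per local calendar day present in the
#'   series: `date`, `tp_halfhours`, `hours`, `is_sva_day`.
#' @export
summarize_days <- function(labels, series, day_threshold_h = 3) {
  stopifnot(inherits(series, "site_series"))
  r <- series$records
  if (length(labels) != nrow(r)) stop("labels not aligned to series records")
  day <- as.Date(r$timestamp)
  tp <- tapply(labels, day, sum)
  out <- data.frame(date = as.Date(names(tp)),
                    tp_halfhours = as.integer(tp))
  out$hours <- out$tp_halfhours / 2
  out$is_sva_day <- out$hours >= day_threshold_h
  rownames(out) <- NULL
  out
}

#' Summarize SVA occurrence per year and per site
#'
#' Counts SVA days (days meeting the duration floor) per calendar year; a
#' year qualifies when it has at least `min_days` SVA days, and the site is
#' included in network-level reporting when any year qualifies. Medians of
#' days per year are taken over all observed years; the median event
#' duration (hours per day) is taken over SVA days only. Years with fewer
#' than 300 observed days are flagged partial but still summarized.
#'
#' @param dailies Data frame from [summarize_days()].
#' @param min_days Minimum SVA days in a year for site inclusion.
#' @return An object of class `site_event_report`: list with `annual` (data
#'   frame year, n_days_observed, sva_days, raw_sva_days, median_hours,
#'   qualifies, partial), `included`, `median_days_per_year`,
#'   `median_hours_per_day`, `pct_years_with_sva`.
#' @export
summarize_site <- function(dailies, min_days = 10) {
  if (!nrow(dailies)) {
    return(structure(list(annual = data.frame(), included = FALSE,
                          median_days_per_year = NA_real_,
                          median_hours_per_day = NA_real_,
                          pct_years_with_sva = NA_real_),
                     class = "site_event_report"))
  }
  yr <- as.integer(format(dailies$date, "%Y"))
  annual <- do.call(rbind, lapply(split(dailies, yr), function(d) {
    data.frame(year = as.integer(format(d$date[1], "%Y")),
               n_days_observed = nrow(d),
               sva_days = sum(d$is_sva_day),
               raw_sva_days = sum(d$tp_halfhours > 0),
               median_hours = if (any(d$is_sva_day))
                 stats::median(d$hours[d$is_sva_day]) else NA_real_)
  }))
  annual$qualifies <- annual$sva_days >= min_days
  annual$partial <- annual$n_days_observed < 300
  rownames(annual) <- NULL
  sva_hours <- dailies$hours[dailies$is_sva_day]
  structure(list(
    annual = annual,
    included = any(annual$qualifies),
    median_days_per_year = stats::median(annual$sva_days),
    median_hours_per_day = if (length(sva_hours)) stats::median(sva_hours)
      else NA_real_,
    pct_years_with_sva = 100 * mean(annual$sva_days >= 1)),
    class = "site_event_report")
}

#' @export
print.site_event_report <- function(x, ...) {
  cat(sprintf("SVA event report: included = %s\n", x$included))
  cat(sprintf("  median %s SVA days/yr, median %s h/day, SVA in %s%% of years\n",
              format(x$median_days_per_year), format(x$median_hours_per_day),
              format(round(x$pct_years_with_sva, 1))))
  invisible(x)
}
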