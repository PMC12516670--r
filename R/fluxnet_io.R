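#' Default FLUXNET column mapping
#'
#' Maps the internal record fields to the ONEFlux/FLUXNET2015 half-hourly
#' column names. Override entries for site dialects (e.g., a different soil
#' moisture sensor column).
#'
#' @param ... Named overrides, e.g. `vwc = "SWC_F_MDS_2"`.
#' @return Named character vector of column names.
#' @export
fluxnet_columns <- function(...) {
  map <- c(timestamp = "TIMESTAMP_START",
           le = "LE_F_MDS", le_qc = "LE_F_MDS_QC",
           vpd = "VPD_F", ta = "TA_F",
           vwc = "SWC_F_MDS_1", precip = "P_F", night = "NIGHT")
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(map))
    if (length(bad)) stop("unknown column-map fields: ", paste(bad, collapse = ", "))
    map[names(ov)] <- ov
  }
  map
}

#' Construct a site series
#'
#' Low-level constructor wrapping a half-hourly record table with site
#' metadata. Most users will obtain one via [read_fluxnet_csv()] or
#' [generate_site()].
#'
#' @param site_id Site identifier.
#' @param records Data frame with columns `timestamp` (POSIXct), `le`,
#'   `le_qc`, `vpd`, `ta`, `vwc`, `precip`, `night`, and optionally derived
#'   `rha`, `valid`.
#' @param meta Named list of free-form site attributes (PFT, aridity class).
#' @return An object of class `site_series`.
#' @export
site_series <- function(site_id, records, meta = list()) {
  req <- c("timestamp", "le", "le_qc", "vpd", "ta", "vwc", "precip", "night")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$timestamp)) stop("duplicate timestamps in series")
  if (is.unsorted(records$timestamp)) {
    records <- records[order(records$timestamp), , drop = FALSE]
  }
  # cadence check: every step a whole number of half hours
  if (nrow(records) > 1) {
    dt <- as.numeric(diff(records$timestamp), units = "mins")
    if (any(dt %% 30 != 0)) stop("timestamps are not on a half-hourly grid")
  }
  rownames(records) <- NULL
  structure(list(site_id = site_id, records = records, meta = meta),
            class = "site_series")
}

#' @export
print.site_series <- function(x, ...) {
  r <- x$records
  cat(sprintf("Site series '%s': %d half hours (%s to %s)\n", x$site_id,
              nrow(r), format(min(r$timestamp)), format(max(r$timestamp))))
  if ("valid" %in% names(r)) {
    cat(sprintf("  valid after filters: %d (%.1f%%)\n",
                sum(r$valid), 100 * mean(r$valid)))
  }
  invisible(x)
}

#' Read a FLUXNET-style half-hourly CSV file
#'
#' Parses 12-digit `TIMESTAMP_START` stamps (YYYYMMDDHHMM, local tower
#' time), maps the -9999 sentinel to `NA`, normalizes soil moisture to
#' vol-% (values reported as m3 m-3, i.e. all <= 1, are multiplied by 100),
#' and derives atmospheric relative humidity from VPD and air temperature
#' via the Magnus equation.
#'
#' @param path CSV file path.
#' @param site_id Site identifier; defaults to the file name stem.
#' @param columns Column mapping from [fluxnet_columns()].
#' @param meta Site metadata list (see [site_series()]).
#' @param constants A [sva_constants()] object for the RHa derivation.
#' @return A [site_series()] with a derived `rha` column (percent).
#' @export
read_fluxnet_csv <- function(path, site_id = NULL,
                             columns = fluxnet_columns(), meta = list(),
                             constants = sva_constants()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss)) {
    stop("mapped column(s) absent from ", basename(path), ": ",
         paste(miss, collapse = ", "))
  }
  d <- data.frame(timestamp = as.POSIXct(as.character(raw[[columns["timestamp"]]]),
                                         format = "%Y%m%d%H%M", tz = "UTC"))
  if (anyNA(d$timestamp)) stop("unparseable TIMESTAMP_START values in ", path)
  for (f in c("le", "le_qc", "vpd", "ta", "vwc", "precip", "night")) {
    v <- as.numeric(raw[[columns[f]]])
    v[v == -9999] <- NA_real_
    d[[f]] <- v
  }
  d$night <- d$night > 0
  # normalize m3/m3 soil moisture to vol-%
  if (all(d$vwc <= 1.5, na.rm = TRUE)) d$vwc <- d$vwc * 100
  d$rha <- ifelse(is.na(d$vpd) | is.na(d$ta), NA_real_,
                  rha_from_vpd(pmax(d$vpd, 0), d$ta, constants))
  site_series(if (is.null(site_id)) sub("\\.csv$", "", basename(path)) else site_id,
              d, meta)
}

#' Apply the quality and meteorological filters
#'
#' Marks records invalid, never dropping or altering them, per the rules the
#' flux-direction analysis requires: only measured, good-quality latent heat
#' flux (QC = 0); whole calendar days with any recorded rain excluded; half
#' hours colder than 5 degrees C excluded; physically implausible soil
#' moisture (<= 0 or > 100 vol-%) excluded; records missing any required
#' field excluded. Each invalid record is attributed to the first failing
#' rule in the order QC, rain day, Ta, VWC, missing.
#'
#' @param series A [site_series()].
#' @param min_ta Minimum air temperature, degrees C.
#' @param rain_day_mm Exclude whole days with total precipitation strictly
#'   above this amount (mm).
#' @param qc_max Maximum accepted LE quality flag (0 = measured, good).
#' @return The series with logical `valid` and character `invalid_reason`
#'   columns, plus a `filter_report` attribute (data frame rule/removed).
#' @export
apply_filters <- function(series, min_ta = 5, rain_day_mm = 0, qc_max = 0) {
  stopifnot(inherits(series, "site_series"))
  r <- series$records
  day <- as.Date(r$timestamp)
  rain_by_day <- tapply(r$precip, day, function(p) sum(p, na.rm = TRUE))
  rain_day <- rain_by_day[as.character(day)] > rain_day_mm

  fail_qc   <- !is.na(r$le_qc) & r$le_qc > qc_max
  fail_rain <- rain_day
  fail_ta   <- !is.na(r$ta) & r$ta < min_ta
  fail_vwc  <- !is.na(r$vwc) & (r$vwc <= 0 | r$vwc > 100)
  fail_miss <- is.na(r$le) | is.na(r$le_qc) | is.na(r$vpd) | is.na(r$ta) |
    is.na(r$vwc) | is.na(r$night) | is.na(r$rha)

  reason <- rep(NA_character_, nrow(r))
  for (rule in c("missing", "vwc", "ta", "rain_day", "qc")) {
    fl <- switch(rule, qc = fail_qc, rain_day = fail_rain, ta = fail_ta,
                 vwc = fail_vwc, missing = fail_miss)
    reason[fl] <- rule   # later assignments win: qc ends up first priority
  }
  r$valid <- is.na(reason)
  r$invalid_reason <- reason
  series$records <- r
  report <- data.frame(rule = c("qc", "rain_day", "ta", "vwc", "missing"))
  report$removed <- vapply(report$rule,
                           function(x) sum(reason == x, na.rm = TRUE), 0L)
  attr(series, "filter_report") <- report
  series
}

#' Restrict a filtered series to valid nighttime records
#'
#' Uses the NIGHT flag carried in the data (the potential-radiation-based
#' classification of the source dataset); no re-derivation is attempted when
#' the flag is present.
#'
#' @param series A [site_series()] that has passed [apply_filters()].
#' @return A [site_series()] containing only valid nighttime records.
#' @export
select_night <- function(series) {
  stopifnot(inherits(series, "site_series"))
  r <- series$records
  if (!"valid" %in% names(r)) stop("run apply_filters() before select_night()")
  if (all(is.na(r$night))) stop("no NIGHT flag present in series")
  series$records <- r[r$valid & !is.na(r$night) & r$night, , drop = FALSE]
  rownames(series$records) <- NULL
  series
}
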