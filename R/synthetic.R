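#' Configuration for the synthetic tower-data generator
#'
#' Defines the conditions of a simulated eddy-covariance site: a diel air
#' temperature sinusoid with day-to-day variability, an air vapor-pressure
#' cycle lagged against temperature so relative humidity peaks at night,
#' rain-pulse plus exponential-drydown soil moisture, nocturnal latent heat
#' flux whose sign follows the vapor gradient implied by a known retention
#' boundary, symmetric nocturnal flux noise, and dew events forced at very
#' high humidity. Defaults describe a semi-arid site over one warm season
#' with a loam-like soil (the truth template `vwc_rh80 = 8.08`) and a
#' nocturnal signal-to-noise ratio of one, which places single half hours
#' well inside the noise but makes binned dominance detectable.
#'
#' @param n_days Number of simulated days.
#' @param seed RNG seed; the series is deterministic given the seed.
#' @param ta_mean,ta_amp Diel air-temperature sinusoid, degrees C (peak at
#'   15:00 local).
#' @param ta_day_sd Day-to-day temperature offset SD, degrees C.
#' @param vp_mean,vp_amp Air vapor pressure mean and diel amplitude, kPa
#'   (peak at 18:00 so RHa peaks in the cold night hours).
#' @param vp_day_sd Day-to-day vapor pressure offset SD, kPa.
#' @param rain_prob_per_day Probability a day carries a rain pulse.
#' @param rain_mm Rain per pulse, mm.
#' @param vwc_wet Soil moisture immediately after rain, vol-%.
#' @param vwc_residual Dry-end soil moisture asymptote, vol-%.
#' @param drydown_efold_days E-folding time of the drydown, days.
#' @param true_vwc_rh80 The generating retention boundary (vol-%).
#' @param day_le_mean Midday latent heat flux, W m-2.
#' @param night_signal Magnitude of the gradient-driven nocturnal flux,
#'   W m-2.
#' @param night_noise_sd SD of the symmetric flux noise, W m-2 (0 gives a
#'   noiseless series).
#' @param noise_family `"gaussian"` (default) or `"laplace"`.
#' @param dew_rha_thresh Atmospheric humidity (percent) above which
#'   nighttime flux is forced negative and flagged as dew; set above 100 to
#'   disable dew.
#' @param start Start timestamp of the series.
#' @return An object of class `synth_config` (named list).
#' @export
synth_config <- function(n_days = 180, seed = 1,
                         ta_mean = 18, ta_amp = 7, ta_day_sd = 2,
                         vp_mean = 1.0, vp_amp = 0.1, vp_day_sd = 0.3,
                         rain_prob_per_day = 0.05, rain_mm = 5,
                         vwc_wet = 28, vwc_residual = 2,
                         drydown_efold_days = 12,
                         true_vwc_rh80 = 8.08,
                         day_le_mean = 120, night_signal = 5,
                         night_noise_sd = 5, noise_family = "gaussian",
                         dew_rha_thresh = 95,
                         start = as.POSIXct("2020-03-01 00:00", tz = "UTC")) {
  cfg <- list(n_days = n_days, seed = seed, ta_mean = ta_mean, ta_amp = ta_amp,
              ta_day_sd = ta_day_sd, vp_mean = vp_mean, vp_amp = vp_amp,
              vp_day_sd = vp_day_sd, rain_prob_per_day = rain_prob_per_day,
              rain_mm = rain_mm, vwc_wet = vwc_wet,
              vwc_residual = vwc_residual,
              drydown_efold_days = drydown_efold_days,
              true_vwc_rh80 = true_vwc_rh80, day_le_mean = day_le_mean,
              night_signal = night_signal, night_noise_sd = night_noise_sd,
              noise_family = match.arg(noise_family, c("gaussian", "laplace")),
              dew_rha_thresh = dew_rha_thresh, start = start)
  sc <- c("n_days", "ta_amp", "vp_mean", "rain_mm", "vwc_wet",
          "drydown_efold_days", "day_le_mean", "night_signal")
  if (any(unlist(cfg[sc]) <= 0)) stop("scale parameters must be positive")
  if (cfg$vwc_residual >= cfg$vwc_wet) stop("vwc_residual must be < vwc_wet")
  if (cfg$night_noise_sd < 0 || cfg$rain_prob_per_day < 0 ||
      cfg$rain_prob_per_day > 1) stop("invalid noise or rain settings")
  structure(cfg, class = "synth_config")
}

# shared machinery: meteorology, soil moisture and noise draws are identical
# across modes for a given seed, so SVA/null/attenuated variants of the same
# site differ only in how the nocturnal flux is assembled
.generate <- function(cfg, mode = c("sva", "null"), signal_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)

  n <- cfg$n_days * 48L
  tstamp <- cfg$start + seq(0, by = 1800, length.out = n)
  dayi <- rep(seq_len(cfg$n_days), each = 48L)
  hod <- rep(seq(0, 23.5, by = 0.5), cfg$n_days)
  night <- hod >= 21 | hod < 7   # fixed 10-h night window

  # random draws, all upfront (identical across modes)
  ta_off <- stats::rnorm(cfg$n_days, 0, cfg$ta_day_sd)
  vp_off <- stats::rnorm(cfg$n_days, 0, cfg$vp_day_sd)
  rain_day <- stats::runif(cfg$n_days) < cfg$rain_prob_per_day
  rain_slot <- sample.int(48L, cfg$n_days, replace = TRUE)
  noise <- if (cfg$noise_family == "gaussian") {
    stats::rnorm(n, 0, cfg$night_noise_sd)
  } else {
    u <- stats::runif(n) - 0.5
    b <- cfg$night_noise_sd / sqrt(2)
    -b * sign(u) * log1p(-2 * abs(u))
  }

  ta <- cfg$ta_mean + ta_off[dayi] + cfg$ta_amp * cos(2 * pi * (hod - 15) / 24)
  e_air <- pmax(cfg$vp_mean + vp_off[dayi] +
                  cfg$vp_amp * cos(2 * pi * (hod - 18) / 24), 0.05)
  esat <- esat_magnus(ta)
  vpd <- pmax(esat - e_air, 0)
  rha <- rha_from_vpd(vpd, ta)

  precip <- numeric(n)
  precip[(which(rain_day) - 1L) * 48L + rain_slot[rain_day]] <- cfg$rain_mm

  k <- exp(-(0.5 / 24) / cfg$drydown_efold_days)
  vwc <- numeric(n)
  v <- (cfg$vwc_wet + cfg$vwc_residual) / 2
  for (i in seq_len(n)) {
    if (precip[i] > 0) v <- cfg$vwc_wet
    v <- cfg$vwc_residual + (v - cfg$vwc_residual) * k
    vwc[i] <- v
  }

  truth_tpl <- evea_template(cfg$true_vwc_rh80, label = "truth")
  rhs <- rhs_from_vwc(truth_tpl, vwc)

  solar <- pmax(sin(pi * (hod - 7) / 14), 0)
  solar[night] <- 0
  le <- cfg$day_le_mean * solar + noise
  dew <- rep(FALSE, n)
  if (mode == "sva") {
    sig <- cfg$night_signal * signal_scale * sign(rhs - rha)
    le[night] <- sig[night] + noise[night]
    dew <- night & rha > cfg$dew_rha_thresh
    # dew deposition is a surface flux too: a decoupled tower sees it
    # attenuated exactly like the adsorption signal
    le[dew] <- signal_scale * (-abs(le[dew])) + (1 - signal_scale) * le[dew]
  } else {
    le[night] <- noise[night]
  }

  records <- data.frame(timestamp = tstamp, le = le, le_qc = 0L,
                        vpd = vpd, ta = ta, vwc = vwc, precip = precip,
                        night = night, rha = rha)
  series <- site_series(sprintf("SYN-%s-%d", toupper(mode), cfg$seed),
                        records,
                        meta = list(pft = "synthetic", mode = mode,
                                    true_vwc_rh80 = if (mode == "sva")
                                      cfg$true_vwc_rh80 else 0))
  truth <- data.frame(timestamp = tstamp,
                      adsorption = if (mode == "sva") night & rha > rhs
                        else rep(FALSE, n),
                      dew = dew, rhs = rhs)
  list(series = series, truth = truth, template = truth_tpl, config = cfg)
}

#' Generate a synthetic SVA site with ground truth
#'
#' Produces a half-hourly series whose nocturnal latent heat flux direction
#' follows the vapor gradient between atmospheric humidity and the pore-air
#' humidity implied by the configured retention boundary, plus symmetric
#' noise and forced-negative dew half hours at very high humidity. The
#' ground-truth table flags every half hour whose true gradient points into
#' the soil (`adsorption`) and every forced dew event (`dew`).
#'
#' @param cfg A [synth_config()].
#' @return List with `series` (a [site_series()]), `truth` (data frame
#'   aligned to the records), `template` (the generating [evea_template()]),
#'   and `config`.
#' @export
generate_site <- function(cfg = synth_config()) .generate(cfg, "sva")

#' Generate a null site (no vapor-gradient signal)
#'
#' Identical meteorology and soil-moisture dynamics to [generate_site()]
#' under the same seed, but the nocturnal flux is pure zero-mean symmetric
#' noise, independent of the gradient — the null hypothesis that flux
#' direction carries no (RHa, VWC) structure.
#'
#' @param cfg A [synth_config()].
#' @return List as in [generate_site()]; `truth$adsorption` is all FALSE.
#' @export
generate_null_site <- function(cfg = synth_config()) .generate(cfg, "null")

#' Generate a co-located short/tall tower pair
#'
#' The short tower sees the full nocturnal gradient signal; the tall tower
#' sees the same meteorology and noise with the signal attenuated by
#' `(1 - decoupling)`, emulating the weaker surface coupling of a tall
#' eddy-covariance system. `decoupling = 1` makes the tall tower's night
#' flux pure noise.
#'
#' @param cfg A [synth_config()].
#' @param decoupling Fraction in [0, 1].
#' @return List with `short` and `tall`, each as in [generate_site()].
#' @export
generate_twin_towers <- function(cfg = synth_config(), decoupling = 0.5) {
  if (decoupling < 0 || decoupling > 1) stop("decoupling must be in [0, 1]")
  short <- .generate(cfg, "sva")
  tall <- .generate(cfg, "sva", signal_scale = 1 - decoupling)
  tall$series$site_id <- sub("SYN-SVA", "SYN-TALL", tall$series$site_id)
  list(short = short, tall = tall)
}

#' Write a synthetic site as a FLUXNET-style CSV
#'
#' Writes the series with ONEFlux-style column names, 12-digit
#' `TIMESTAMP_START` stamps and -9999 sentinels, plus an optional
#' ground-truth sidecar CSV, so the file round-trips through
#' [read_fluxnet_csv()].
#'
#' @param site Output of [generate_site()] (or `$short`/`$tall` of a twin
#'   pair).
#' @param path Output CSV path.
#' @param truth_path Optional path for the ground-truth sidecar.
#' @return `path`, invisibly.
#' @export
write_fluxnet_csv <- function(site, path, truth_path = NULL) {
  r <- site$series$records
  out <- data.frame(TIMESTAMP_START = format(r$timestamp, "%Y%m%d%H%M"),
                    LE_F_MDS = r$le, LE_F_MDS_QC = r$le_qc,
                    VPD_F = r$vpd, TA_F = r$ta, SWC_F_MDS_1 = r$vwc,
                    P_F = r$precip, NIGHT = as.integer(r$night))
  for (cc in names(out)) out[[cc]][is.na(out[[cc]])] <- -9999
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    tr <- site$truth
    tr$timestamp <- format(tr$timestamp, "%Y%m%d%H%M")
    utils::write.csv(tr, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
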