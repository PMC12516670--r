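#' Build a vapor-equilibrium boundary template
#'
#' A template is the zero-vapor-gradient curve in (RHa, VWC) space for one
#' soil: the equilibrium water content `vwc_eq(RH)` below which the pore-air
#' humidity falls short of the atmosphere, so the vapor gradient points into
#' the soil and adsorption is physically possible. Templates are indexed by a
#' single parameter, `vwc_rh80`, the volumetric water content in equilibrium
#' with 80% relative humidity (a water potential of roughly -302,000 hPa at
#' the 20 degree C reference temperature).
#'
#' The parametric curve is log-linear in potential (Campbell-Shiozawa form),
#' anchored at (RH = 80%, vwc_rh80) and at zero water content oven-dry
#' (pF = 6.8 by default):
#' \deqn{VWC_{eq}(RH) = vwc_{RH80}\,
#'   \frac{1 - pF(RH)/pF_{dry}}{1 - pF(0.80)/pF_{dry}}}
#' truncated below at 0, where pF is log10 of suction in hPa from the Kelvin
#' equation at the reference temperature. `vwc_rh80 = 0` gives the null
#' template, whose curve is identically zero (adsorption predicted nowhere).
#'
#' Users with laboratory retention measurements in the dry range can supply
#' `anchors`, a data frame of (rh fraction, vwc vol-%) pairs; the boundary is
#' then piecewise-linear interpolation in (ln RH, VWC) through the anchors
#' instead of the parametric form.
#'
#' @param vwc_rh80 Volumetric water content (vol-%) in equilibrium with 80%
#'   RH; >= 0. Zero gives the null template.
#' @param psi_dry Oven-dry potential anchor in hPa (negative); the water
#'   content is taken as zero there. Default -10^6.8 hPa.
#' @param label Free-text label (e.g., a USDA texture name).
#' @param anchors Optional data frame with columns `rh` (fraction in (0, 1])
#'   and `vwc` (vol-%), at least two rows, monotone non-decreasing vwc in rh.
#' @param ref_temp_K Reference temperature for RH-to-potential conversion
#'   inside the curve, K.
#' @param constants A [sva_constants()] object.
#' @return An object of class `evea_template`.
#' @examples
#' clay <- evea_template(11.03, label = "pure clay")
#' vwc_eq(clay, 80)  # 11.03 by construction
#' @export
evea_template <- function(vwc_rh80, psi_dry = -10^6.8, label = NULL,
                          anchors = NULL, ref_temp_K = 293.15,
                          constants = sva_constants()) {
  if (!is.numeric(vwc_rh80) || length(vwc_rh80) != 1 || !is.finite(vwc_rh80) ||
      vwc_rh80 < 0) {
    stop("vwc_rh80 must be a single non-negative number (vol-%)")
  }
  pf80 <- log10(-psi_from_rh(0.80, ref_temp_K, constants) / 100)
  if (!(psi_dry < 0) || log10(-psi_dry) <= pf80) {
    stop("psi_dry must be a suction drier than the 80% RH potential")
  }
  if (!is.null(anchors)) {
    anchors <- as.data.frame(anchors)
    if (!all(c("rh", "vwc") %in% names(anchors)) || nrow(anchors) < 2) {
      stop("anchors need columns 'rh' and 'vwc' and at least two rows")
    }
    if (any(anchors$rh <= 0 | anchors$rh > 1)) {
      stop("anchor rh values must lie in (0, 1]")
    }
    anchors <- anchors[order(anchors$rh), , drop = FALSE]
    if (is.unsorted(anchors$vwc)) {
      stop("anchor vwc must be non-decreasing in rh (monotone retention)")
    }
  }
  structure(
    list(vwc_rh80 = vwc_rh80, psi_dry = psi_dry,
         label = if (is.null(label)) sprintf("VWC_RH80=%.2f", vwc_rh80) else label,
         anchors = anchors, ref_temp_K = ref_temp_K, constants = constants,
         pf80 = pf80, pf_dry = log10(-psi_dry)),
    class = "evea_template")
}

#' @export
print.evea_template <- function(x, ...) {
  kind <- if (x$vwc_rh80 == 0) "null template" else
    if (is.null(x$anchors)) "parametric (log-linear in pF)" else
      sprintf("data-driven (%d anchors)", nrow(x$anchors))
  cat(sprintf("EVEa template '%s': VWC_RH80 = %.2f vol-%% [%s]\n",
              x$label, x$vwc_rh80, kind))
  invisible(x)
}

#' Equilibrium water content of a template at a given atmospheric humidity
#'
#' Evaluates the template boundary curve. At exactly 100% RH the parametric
#' curve is unbounded (zero suction); `Inf` is returned there for non-null
#' templates, meaning any water content is below saturation equilibrium.
#'
#' @param template An [evea_template()].
#' @param rha Atmospheric relative humidity in percent, in [0, 100].
#'   Vectorized.
#' @return Equilibrium VWC in vol-%, >= 0.
#' @export
vwc_eq <- function(template, rha) {
  stopifnot(inherits(template, "evea_template"))
  if (any(rha < 0 | rha > 100, na.rm = TRUE)) {
    stop("rha must lie in [0, 100] percent")
  }
  if (template$vwc_rh80 == 0) return(rep(0, length(rha)))
  rh <- rha / 100
  if (!is.null(template$anchors)) {
    a <- template$anchors
    out <- stats::approx(log(a$rh), a$vwc, xout = log(pmax(rh, 1e-12)),
                         rule = 2)$y
    return(pmax(out, 0))
  }
  out <- numeric(length(rh))
  pos <- !is.na(rh) & rh > 0
  out[!pos & !is.na(rh)] <- 0
  psi_hpa <- psi_from_rh(rh[pos], template$ref_temp_K, template$constants) / 100
  pf <- suppressWarnings(log10(-psi_hpa))   # -Inf at rh = 1 -> Inf vwc
  scale <- (1 - pf / template$pf_dry) / (1 - template$pf80 / template$pf_dry)
  out[pos] <- pmax(template$vwc_rh80 * scale, 0)
  out[is.na(rh)] <- NA_real_
  out
}

#' Is soil vapor adsorption physically possible at a point?
#'
#' TRUE iff the water content lies strictly below the template boundary at
#' the given atmospheric humidity, i.e., soil pore-air humidity below
#' atmospheric and the vapor gradient directed into the soil. Points exactly
#' on the boundary count as not possible (conservative tie rule); the null
#' template returns FALSE everywhere.
#'
#' @param template An [evea_template()].
#' @param rha Atmospheric relative humidity, percent. Vectorized.
#' @param vwc Volumetric water content, vol-% (>= 0). Vectorized.
#' @return Logical vector.
#' @export
is_sva_possible <- function(template, rha, vwc) {
  if (any(vwc < 0, na.rm = TRUE)) stop("vwc must be >= 0")
  vwc < vwc_eq(template, rha)
}

#' Soil pore-air relative humidity from water content (inverse boundary)
#'
#' Inverts the template's equilibrium curve: the pore-air relative humidity
#' a soil at the given water content equilibrates to. Water contents at or
#' above the curve's range (wet soil) return 100% — pore air saturated.
#' For the null template the pore air is treated as saturated everywhere.
#'
#' @param template An [evea_template()].
#' @param vwc Volumetric water content, vol-% (>= 0). Vectorized.
#' @return Soil relative humidity in percent, in (0, 100].
#' @export
rhs_from_vwc <- function(template, vwc) {
  stopifnot(inherits(template, "evea_template"))
  if (any(vwc < 0, na.rm = TRUE)) stop("vwc must be >= 0")
  if (template$vwc_rh80 == 0) return(rep(100, length(vwc)))
  if (!is.null(template$anchors)) {
    a <- template$anchors
    lnrh <- stats::approx(a$vwc, log(a$rh), xout = vwc, rule = 2)$y
    out <- 100 * exp(lnrh)
    out[vwc >= max(a$vwc)] <- 100 * max(a$rh)
    return(out)
  }
  # closed-form inverse of the log-linear (pF) curve
  pf <- template$pf_dry * (1 - (vwc / template$vwc_rh80) *
                             (1 - template$pf80 / template$pf_dry))
  psi_pa <- -100 * 10^pf
  out <- 100 * rh_from_psi(psi_pa, template$ref_temp_K, template$constants)
  pmin(out, 100)
}

# default 11-point texture grid: synthetic stand-in spanning sand -> clay,
# including the pure-clay end member (VWC_RH80 = 11.03)
.texture_grid_default <- c(0.5, 1.0, 1.6, 2.31, 3.2, 4.20, 5.5, 7.0,
                           8.08, 9.5, 11.03)

#' Build a library of boundary templates
#'
#' A template library always contains exactly one null template
#' (`vwc_rh80 = 0`) — the baseline for the null hypothesis that flux
#' direction is independent of humidity and soil moisture — plus one
#' template per distinct positive value, sorted ascending.
#'
#' @param values Numeric vector of `vwc_rh80` values (vol-%). The default
#'   combines an 11-point texture grid spanning sand to pure clay with the
#'   best-fit values reported for reference dryland and forest sites
#'   (2.31, 4.20, 8.08, 11.0, 11.03).
#' @param ... Passed to [evea_template()] (e.g., `psi_dry`, `ref_temp_K`).
#' @return An object of class `template_library`: a list of templates
#'   ordered by `vwc_rh80`, starting with the null template.
#' @export
template_library <- function(values = unique(c(.texture_grid_default,
                                               2.31, 4.20, 8.08, 11.0)), ...) {
  if (any(values < 0, na.rm = TRUE)) stop("template values must be >= 0")
  values <- values[is.finite(values) & values > 0]
  if (anyDuplicated(values)) {
    warning("duplicate vwc_rh80 values dropped")
    values <- unique(values)
  }
  values <- sort(values)
  tpls <- c(list(evea_template(0, label = "null", ...)),
            lapply(values, function(v) evea_template(v, ...)))
  structure(tpls, class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("EVEa template library: %d templates (incl. null)\n", length(x)))
  cat("  VWC_RH80:", paste(sprintf("%.2f", vapply(x, `[[`, 0, "vwc_rh80")),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Read laboratory retention anchors for a data-driven template
#'
#' Reads a CSV with columns `rh` (fraction) and `vwc` (vol-%) and builds a
#' template whose boundary interpolates the measured pairs; `vwc_rh80` is
#' taken from the interpolated curve at RH = 80%.
#'
#' @param path Path to the anchors CSV.
#' @param label Template label; defaults to the file name.
#' @param ... Passed to [evea_template()].
#' @return An [evea_template()] with anchors.
#' @export
read_template_anchors <- function(path, label = NULL, ...) {
  a <- utils::read.csv(path)
  if (!all(c("rh", "vwc") %in% names(a))) {
    stop("anchor file must have columns 'rh' and 'vwc': ", path)
  }
  if (max(a$rh) > 1) a$rh <- a$rh / 100   # accept percent
  tmp <- evea_template(1, anchors = a, label = label, ...)
  v80 <- vwc_eq(tmp, 80)
  evea_template(v80, anchors = a,
                label = if (is.null(label)) basename(path) else label, ...)
}
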