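#' Bin nighttime observations in (RHa, VWC) space
#'
#' Groups half-hourly records into a rectangular grid of humidity x soil
#' moisture cells and counts, per cell, the total observations and those with
#' negative latent heat flux. Cells are half-open intervals [lo, hi); the
#' topmost humidity cell additionally absorbs RHa = 100 exactly. The grid
#' tiles [0, 100] percent RHa by [0, vwc_max] vol-% (vwc_max rounded up to a
#' whole cell).
#'
#' @param series A [site_series()] of valid records with `rha`, `vwc`, `le`
#'   (typically the output of [select_night()]).
#' @param rha_width RHa bin width, percent.
#' @param vwc_width VWC bin width, vol-%.
#' @return An object of class `bin_grid`: a data frame of cells with columns
#'   `rha_lo`, `rha_hi`, `vwc_lo`, `vwc_hi`, `n_total`, `n_negative`,
#'   `fraction_negative`, plus attributes recording widths and provenance.
#' @export
assign_bins <- function(series, rha_width = 5, vwc_width = 2) {
  stopifnot(inherits(series, "site_series"))
  r <- series$records
  keep <- !is.na(r$rha) & !is.na(r$vwc) & !is.na(r$le)
  r <- r[keep, , drop = FALSE]
  n_rha <- ceiling(100 / rha_width)
  vwc_max <- if (nrow(r)) max(r$vwc) else 0
  n_vwc <- max(1L, ceiling(vwc_max / vwc_width + 1e-9))

  cells <- expand.grid(i_rha = seq_len(n_rha), i_vwc = seq_len(n_vwc))
  cells$rha_lo <- (cells$i_rha - 1) * rha_width
  cells$rha_hi <- cells$i_rha * rha_width
  cells$vwc_lo <- (cells$i_vwc - 1) * vwc_width
  cells$vwc_hi <- cells$i_vwc * vwc_width
  cells$n_total <- 0L
  cells$n_negative <- 0L

  if (nrow(r)) {
    i_rha <- pmin(floor(r$rha / rha_width) + 1L, n_rha)  # rha = 100 -> top cell
    i_vwc <- pmin(floor(r$vwc / vwc_width) + 1L, n_vwc)
    idx <- (i_vwc - 1L) * n_rha + i_rha
    tot <- tabulate(idx, nbins = n_rha * n_vwc)
    neg <- tabulate(idx[r$le < 0], nbins = n_rha * n_vwc)
    cells$n_total <- tot
    cells$n_negative <- neg
  }
  cells$fraction_negative <- ifelse(cells$n_total > 0,
                                    cells$n_negative / cells$n_total, NA_real_)
  cells$i_rha <- cells$i_vwc <- NULL
  pts <- if (nrow(r)) data.frame(rha = r$rha, vwc = r$vwc, neg = r$le < 0,
                                 cell = (pmin(floor(r$vwc / vwc_width) + 1L,
                                              n_vwc) - 1L) * n_rha +
                                   pmin(floor(r$rha / rha_width) + 1L, n_rha))
    else data.frame(rha = numeric(), vwc = numeric(), neg = logical(),
                    cell = integer())
  structure(cells, class = c("bin_grid", "data.frame"),
            rha_width = rha_width, vwc_width = vwc_width,
            site_id = series$site_id, n_records = nrow(r), points = pts)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("Flux-direction bin grid for '%s': %d cells (%g%% RHa x %g vol-%% VWC), %d records\n",
              attr(x, "site_id"), nrow(x), attr(x, "rha_width"),
              attr(x, "vwc_width"), attr(x, "n_records")))
  if ("direction" %in% names(x)) print(table(x$direction[x$n_total > 0]))
  invisible(x)
}

#' Classify the dominant flux direction of each bin
#'
#' A bin with at least `min_n` observations is classified by its fraction of
#' negative latent heat fluxes: dominantly toward the atmosphere when the
#' fraction is below `lo`, dominantly toward the soil when above `hi`, and
#' random noise in between (both bounds inclusive), consistent with a
#' symmetric distribution of random flux error. Bins with fewer than `min_n`
#' observations are marked insufficient.
#'
#' @param grid A [assign_bins()] grid.
#' @param min_n Minimum observations per bin.
#' @param lo,hi Dominance thresholds on the negative-flux fraction.
#' @return The grid with a `direction` factor column with levels
#'   `atmosphere`, `soil`, `noise`, `insufficient`.
#' @export
classify_bins <- function(grid, min_n = 20, lo = 0.45, hi = 0.55) {
  stopifnot(inherits(grid, "bin_grid"))
  if (lo >= hi) stop("dominance thresholds require lo < hi")
  dir <- rep(NA_character_, nrow(grid))
  enough <- grid$n_total >= min_n
  dir[!enough] <- "insufficient"
  dir[enough & grid$fraction_negative < lo] <- "atmosphere"
  dir[enough & grid$fraction_negative > hi] <- "soil"
  dir[enough & grid$fraction_negative >= lo & grid$fraction_negative <= hi] <- "noise"
  grid$direction <- factor(dir, levels = c("atmosphere", "soil", "noise",
                                           "insufficient"))
  attr(grid, "min_n") <- min_n
  attr(grid, "thresholds") <- c(lo = lo, hi = hi)
  grid
}

#' Dew-exclusion mask over grid cells
#'
#' Negative latent heat flux at high atmospheric humidity can reflect dew or
#' fog deposition rather than soil vapor adsorption. Cells whose whole RHa
#' range lies at or above the dew threshold, and whose soil moisture is too
#' high for adsorption under the given template (cell center on or above the
#' boundary), are excluded from template scoring.
#'
#' @param grid A classified [bin_grid].
#' @param template An [evea_template()].
#' @param rha_thresh Dew-likelihood humidity threshold, percent.
#' @return Logical vector over cells, TRUE = excluded.
#' @export
dew_exclusion <- function(grid, template, rha_thresh = 75) {
  stopifnot(inherits(grid, "bin_grid"))
  ctr_rha <- (grid$rha_lo + grid$rha_hi) / 2
  ctr_vwc <- (grid$vwc_lo + grid$vwc_hi) / 2
  grid$rha_lo >= rha_thresh & !is_sva_possible(template, ctr_rha, ctr_vwc)
}

#' Template-predicted positive cells
#'
#' A cell is predicted positive (adsorption expected to dominate) when the
#' fraction of its observations lying strictly below the template boundary
#' exceeds the dominance threshold `hi` — the same cut applied to the
#' observed negative-flux fraction by [classify_bins()]. Evaluating the
#' prediction on the cell's own observations, rather than at a fixed point
#' such as the cell center, keeps prediction and observation commensurate:
#' on a noiseless series the two fractions coincide cell by cell.
#'
#' @param grid A [bin_grid].
#' @param template An [evea_template()].
#' @param hi Dominance threshold; defaults to the one recorded by
#'   [classify_bins()], else 0.55.
#' @return Logical vector over cells (FALSE for empty cells).
#' @export
predict_cells <- function(grid, template, hi = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  if (is.null(hi)) {
    th <- attr(grid, "thresholds")
    hi <- if (is.null(th)) 0.55 else th[["hi"]]
  }
  pts <- attr(grid, "points")
  pred <- rep(FALSE, nrow(grid))
  if (nrow(pts)) {
    below <- is_sva_possible(template, pts$rha, pts$vwc)
    n_below <- tabulate(pts$cell[below], nbins = nrow(grid))
    pred[grid$n_total > 0] <-
      (n_below / grid$n_total)[grid$n_total > 0] > hi
  }
  pred
}

#' Score one template against the observed flux directions
#'
#' Compares the template's predicted dominant direction (see
#' [predict_cells()]) with the observed one over every sufficiently
#' populated bin that is not dew-excluded. Soil-dominant is the positive
#' class. Noise-band bins — no dominant direction — count as observed
#' negatives by default (`noise = "negative"`): the classifier claims
#' dominant downward flux, and an indeterminate bin does not support that
#' claim. `noise = "exclude"` drops them from the table instead.
#' Insufficient bins are always set aside. Fractions with a zero
#' denominator are `NA`.
#'
#' @param grid A classified [bin_grid].
#' @param template An [evea_template()].
#' @param rha_thresh Dew threshold passed to [dew_exclusion()].
#' @param noise Treatment of noise-band bins: `"negative"` (observed
#'   non-SVA, default) or `"exclude"`.
#' @return An object of class `confusion_summary`: list with counts `tp`,
#'   `fp`, `tn`, `fn`, `n_noise`, `n_excluded_dew`, `n_insufficient`,
#'   fractions `acc`, `tpf`, `fpf`, `tnf`, and `scorable` (FALSE when no
#'   cells survive).
#' @export
score_template <- function(grid, template, rha_thresh = 75,
                           noise = c("negative", "exclude")) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!"direction" %in% names(grid)) stop("classify_bins() must be run first")
  noise <- match.arg(noise)
  dew <- dew_exclusion(grid, template, rha_thresh)
  occupied <- grid$n_total > 0
  insuff <- occupied & grid$direction == "insufficient"
  noisy <- occupied & grid$direction == "noise"
  eligible <- if (noise == "negative") {
    occupied & grid$direction %in% c("atmosphere", "soil", "noise")
  } else {
    occupied & grid$direction %in% c("atmosphere", "soil")
  }
  dewx <- eligible & dew
  use <- eligible & !dew

  pred <- predict_cells(grid, template)
  obs_soil <- grid$direction == "soil"

  tp <- sum(use & pred & obs_soil)
  fp <- sum(use & pred & !obs_soil)
  fn <- sum(use & !pred & obs_soil)
  tn <- sum(use & !pred & !obs_soil)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_noise = sum(noisy), n_excluded_dew = sum(dewx),
    n_insufficient = sum(insuff), noise_treatment = noise,
    acc = frac(tp + tn, tp + tn + fp + fn),
    tpf = frac(tp, tp + fn),
    fpf = frac(fp, fp + tn),
    tnf = if (fp + tn > 0) 1 - frac(fp, fp + tn) else NA_real_,
    scorable = (tp + tn + fp + fn) > 0,
    vwc_rh80 = template$vwc_rh80, label = template$label),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Template %s: TP=%d FP=%d TN=%d FN=%d | ACC=%s TPF=%s FPF=%s\n",
              x$label, x$tp, x$fp, x$tn, x$fn,
              format(round(x$acc, 3)), format(round(x$tpf, 3)),
              format(round(x$fpf, 3))))
  cat(sprintf("  set aside: %d noise, %d dew-excluded, %d insufficient\n",
              x$n_noise, x$n_excluded_dew, x$n_insufficient))
  invisible(x)
}

#' Select the best-fitting template for a site
#'
#' Scores every template in the library against the classified grid and
#' selects the one with the highest accuracy; ties are broken toward the
#' smaller `vwc_rh80` (the more conservative boundary). The null template's
#' accuracy is the baseline under the null hypothesis that flux direction is
#' independent of humidity and soil moisture; selecting the null template
#' means adsorption is absent or undetectable at the site.
#'
#' @param grid A classified [bin_grid].
#' @param library A [template_library()] (must contain the null template).
#' @param rha_thresh Dew threshold passed to scoring.
#' @param noise Noise-bin treatment passed to [score_template()].
#' @return An object of class `site_fit`: list with `per_template` (data
#'   frame of scores), `scores` (the confusion summaries), `best_template`,
#'   `best` (its summary), `acc_baseline`, `acc_best`, `improvement`,
#'   `scorable`.
#' @export
fit_site <- function(grid, library, rha_thresh = 75,
                     noise = c("negative", "exclude")) {
  stopifnot(inherits(grid, "bin_grid"), inherits(library, "template_library"))
  noise <- match.arg(noise)
  v80 <- vapply(library, `[[`, 0, "vwc_rh80")
  if (!any(v80 == 0)) stop("library must contain the null template")
  scores <- lapply(library, score_template, grid = grid,
                   rha_thresh = rha_thresh, noise = noise)
  acc <- vapply(scores, function(s) ifelse(is.na(s$acc), -Inf, s$acc), 0)
  tab <- data.frame(vwc_rh80 = v80,
                    label = vapply(library, `[[`, "", "label"),
                    tp = vapply(scores, `[[`, 0L, "tp"),
                    fp = vapply(scores, `[[`, 0L, "fp"),
                    tn = vapply(scores, `[[`, 0L, "tn"),
                    fn = vapply(scores, `[[`, 0L, "fn"),
                    acc = vapply(scores, `[[`, 0, "acc"),
                    tpf = vapply(scores, `[[`, 0, "tpf"),
                    fpf = vapply(scores, `[[`, 0, "fpf"))
  base_i <- which(v80 == 0)[1]
  scorable <- scores[[base_i]]$scorable
  if (!scorable) {
    best_i <- base_i
  } else {
    # max accuracy; ties toward smaller vwc_rh80 (library is sorted ascending)
    best_i <- which(acc == max(acc))[1]
  }
  structure(list(
    site_id = attr(grid, "site_id"),
    per_template = tab, scores = scores,
    best_template = library[[best_i]], best = scores[[best_i]],
    acc_baseline = scores[[base_i]]$acc, acc_best = scores[[best_i]]$acc,
    improvement = if (scorable) scores[[best_i]]$acc - scores[[base_i]]$acc else 0,
    scorable = scorable), class = "site_fit")
}

#' @export
print.site_fit <- function(x, ...) {
  cat(sprintf("Site fit '%s': best template VWC_RH80 = %.2f vol-%%\n",
              x$site_id, x$best_template$vwc_rh80))
  cat(sprintf("  baseline ACC = %s, best ACC = %s, improvement = %s\n",
              format(round(x$acc_baseline, 3)), format(round(x$acc_best, 3)),
              format(round(x$improvement, 3))))
  if (!x$scorable) cat("  [unscorable grid: no directional bins]\n")
  invisible(x)
}

#' Export a grid as a fraction-negative matrix
#'
#' Rows are VWC bins (ascending), columns RHa bins; entries are the fraction
#' of negative latent heat fluxes (NA where a bin is empty). Suitable for
#' heat-map rendering or CSV export.
#'
#' @param grid A [bin_grid].
#' @return Numeric matrix with informative dimnames.
#' @export
grid_matrix <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  rha_lo <- sort(unique(grid$rha_lo))
  vwc_lo <- sort(unique(grid$vwc_lo))
  m <- matrix(NA_real_, nrow = length(vwc_lo), ncol = length(rha_lo),
              dimnames = list(sprintf("vwc_%g", vwc_lo),
                              sprintf("rha_%g", rha_lo)))
  m[cbind(match(grid$vwc_lo, vwc_lo), match(grid$rha_lo, rha_lo))] <-
    grid$fraction_negative
  m
}
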