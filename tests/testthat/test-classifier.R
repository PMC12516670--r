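test_that("records land in half-open bins and counts are conserved", {
  cells <- data.frame(rha = c(72.5, 75.0), vwc = c(9.1, 9.1),
                      n = c(1, 1), n_neg = c(0, 0))
  s <- make_cluster_series(cells)
  grid <- assign_bins(select_night(s))
  hit <- grid[grid$n_total > 0, ]
  expect_equal(nrow(hit), 2)
  one <- hit[hit$rha_lo == 70, ]
  expect_equal(unlist(one[c("rha_lo", "rha_hi", "vwc_lo", "vwc_hi")]),
               c(rha_lo = 70, rha_hi = 75, vwc_lo = 8, vwc_hi = 10))
  # 75.0 exactly belongs to [75, 80), not [70, 75)
  expect_equal(hit$rha_lo[hit$n_total > 0 & hit$rha_lo != 70], 75)

  g <- generate_site(synth_config(n_days = 120, seed = 7))
  nightly <- select_night(apply_filters(g$series))
  grid2 <- assign_bins(nightly)
  expect_equal(sum(grid2$n_total), nrow(nightly$records))
  expect_equal(attr(grid2, "n_records"), nrow(nightly$records))
})

test_that("per-cell negative fractions match a brute-force recount", {
  g <- generate_site(synth_config(n_days = 90, seed = 11))
  nightly <- select_night(apply_filters(g$series))
  grid <- assign_bins(nightly)
  r <- nightly$records
  top <- max(grid$rha_hi)
  for (i in which(grid$n_total > 0 | grid$rha_lo >= 60)) {
    b <- brute_count(r, grid$rha_lo[i], grid$rha_hi[i],
                     grid$vwc_lo[i], grid$vwc_hi[i],
                     top_rha = grid$rha_hi[i] == top)
    expect_equal(grid$n_total[i], unname(b["n"]))
    expect_equal(grid$n_negative[i], unname(b["neg"]))
  }
  occ <- grid$n_total > 0
  expect_equal(grid$fraction_negative[occ],
               (grid$n_negative / grid$n_total)[occ])
})

test_that("bins are classified by the dominance thresholds inclusively", {
  cells <- data.frame(rha = c(32, 42, 52, 62, 72),
                      vwc = c(5, 5, 5, 5, 5),
                      n = c(20, 20, 20, 19, 20),
                      n_neg = c(12, 9, 11, 19, 5))
  s <- make_cluster_series(cells)
  grid <- classify_bins(assign_bins(select_night(s)))
  get_dir <- function(rha) as.character(
    grid$direction[grid$rha_lo <= rha & grid$rha_hi > rha & grid$n_total > 0])
  expect_equal(get_dir(32), "soil")          # 12/20 = 0.60 > 0.55
  expect_equal(get_dir(42), "noise")         # 9/20 = 0.45, boundary inclusive
  expect_equal(get_dir(52), "noise")         # 11/20 = 0.55, boundary inclusive
  expect_equal(get_dir(62), "insufficient")  # 19 obs < 20
  expect_equal(get_dir(72), "atmosphere")    # 5/20 = 0.25 < 0.45
  expect_error(classify_bins(grid, lo = 0.6, hi = 0.5), "lo < hi")
})

test_that("dew exclusion removes only wet high-humidity cells", {
  clay <- evea_template(11.03, label = "pure clay")
  cells <- data.frame(rha = c(82, 82, 72),
                      vwc = c(21, 3, 21), n = 20, n_neg = 20)
  s <- make_cluster_series(cells)
  grid <- classify_bins(assign_bins(select_night(s)))
  mask <- dew_exclusion(grid, clay)
  wet_high <- grid$rha_lo == 80 & grid$vwc_lo == 20
  dry_high <- grid$rha_lo == 80 & grid$vwc_lo == 2
  wet_low <- grid$rha_lo == 70 & grid$vwc_lo == 20
  expect_true(all(mask[wet_high]))           # 21 vol-% above the boundary
  expect_false(any(mask[dry_high]))          # 3 vol-% is SVA-possible
  expect_false(any(mask[wet_low]))           # below the 75% threshold
  expect_false(any(mask[grid$rha_hi <= 75]))
})

test_that("a hand-built confusion table scores exactly", {
  tpl <- evea_template(8.08)
  # four cells at rha ~62: boundary there is ~5.9 vol-%
  expect_gt(vwc_eq(tpl, 62.5), 4)
  expect_lt(vwc_eq(tpl, 62.5), 8)
  cells <- data.frame(rha = c(62, 62, 62, 62),
                      vwc = c(3, 4.5, 21, 23),
                      n = 20,
                      n_neg = c(18, 2, 2, 18))   # soil, atm, atm, soil
  s <- make_cluster_series(cells)
  grid <- classify_bins(assign_bins(select_night(s)))
  sc <- score_template(grid, tpl)
  expect_equal(c(sc$tp, sc$fp, sc$tn, sc$fn), c(1, 1, 1, 1))
  expect_equal(sc$acc, 0.5)
  expect_equal(sc$tpf, 0.5)
  expect_equal(sc$fpf, 0.5)
  expect_equal(sc$tnf, 0.5)
})

test_that("metric denominators of zero give NA, not errors", {
  cells <- data.frame(rha = 62, vwc = 21, n = 20, n_neg = 2)  # atm only
  s <- make_cluster_series(cells)
  grid <- classify_bins(assign_bins(select_night(s)))
  sc <- score_template(grid, evea_template(0))
  expect_equal(sc$acc, 1)
  expect_true(is.na(sc$tpf))    # no actual positives anywhere
})

test_that("noise bins count as observed negatives by default, or drop", {
  tpl <- evea_template(8.08)
  cells <- data.frame(rha = c(62, 62), vwc = c(3, 4.5),
                      n = 20, n_neg = c(18, 10))   # soil + noise (0.5)
  s <- make_cluster_series(cells)
  grid <- classify_bins(assign_bins(select_night(s)))
  neg <- score_template(grid, tpl, noise = "negative")
  exc <- score_template(grid, tpl, noise = "exclude")
  expect_equal(neg$n_noise, 1)
  expect_equal(exc$n_noise, 1)
  expect_equal(c(neg$tp, neg$fp), c(1, 1))   # noise cell predicted positive
  expect_equal(c(exc$tp, exc$fp), c(1, 0))   # dropped from the table
})

test_that("cell categories are disjoint and sum to occupied cells", {
  g <- generate_site(synth_config(n_days = 120, seed = 5))
  grid <- classify_bins(assign_bins(select_night(apply_filters(g$series))))
  for (mode in c("negative", "exclude")) {
    sc <- score_template(grid, evea_template(8.08), noise = mode)
    confusion <- sc$tp + sc$fp + sc$tn + sc$fn
    extra <- if (mode == "negative") 0 else sc$n_noise
    expect_equal(confusion + extra + sc$n_excluded_dew + sc$n_insufficient,
                 sum(grid$n_total > 0))
  }
})

test_that("the null baseline equals the fraction of non-soil cells", {
  g <- generate_site(synth_config(n_days = 120, seed = 9))
  grid <- classify_bins(assign_bins(select_night(apply_filters(g$series))))
  sc <- score_template(grid, evea_template(0))
  use <- grid$n_total >= 20 &
    grid$direction %in% c("atmosphere", "soil", "noise") &
    !dew_exclusion(grid, evea_template(0))
  expect_equal(sc$acc, mean(grid$direction[use] != "soil"))
  expect_equal(sc$fp + sc$tp, 0)             # null predicts nothing positive
})

test_that("predicted-positive area grows with the template (nesting)", {
  g <- generate_site(synth_config(n_days = 150, seed = 13))
  grid <- classify_bins(assign_bins(select_night(apply_filters(g$series))))
  tpfp <- vapply(default_lib, function(t) {
    sc <- score_template(grid, t)
    sc$tp + sc$fp
  }, numeric(1))
  expect_true(all(diff(tpfp) >= 0))
})

test_that("fit_site selects by accuracy with ties toward the smaller template", {
  # no soil-dominant cells: the null template wins with zero improvement
  cells <- data.frame(rha = c(42, 62), vwc = c(3, 21), n = 20, n_neg = 2)
  s <- make_cluster_series(cells)
  grid <- classify_bins(assign_bins(select_night(s)))
  fit <- fit_site(grid, default_lib)
  expect_equal(fit$best_template$vwc_rh80, 0)
  expect_equal(fit$improvement, 0)

  # one soil cell deep below every positive boundary: all positive templates
  # tie at accuracy 1; the smallest must win
  cells2 <- data.frame(rha = c(62, 30), vwc = c(0.5, 25), n = 20,
                       n_neg = c(19, 1))
  s2 <- make_cluster_series(cells2)
  grid2 <- classify_bins(assign_bins(select_night(s2)))
  lib <- template_library(c(4.2, 8.08, 11.03))
  fit2 <- fit_site(grid2, lib)
  accs <- fit2$per_template$acc
  expect_equal(max(accs), 1)
  expect_equal(fit2$best_template$vwc_rh80, min(
    fit2$per_template$vwc_rh80[accs == 1]))
  expect_gte(fit2$acc_best, fit2$acc_baseline)
})

test_that("an unscorable grid yields a flagged null fit", {
  cells <- data.frame(rha = 62, vwc = 5, n = 5, n_neg = 5)  # insufficient
  s <- make_cluster_series(cells)
  grid <- classify_bins(assign_bins(select_night(s)))
  fit <- fit_site(grid, default_lib)
  expect_false(fit$scorable)
  expect_equal(fit$best_template$vwc_rh80, 0)
})

test_that("grid matrices have one row per VWC bin and column per RHa bin", {
  g <- generate_site(synth_config(n_days = 60, seed = 2))
  grid <- assign_bins(select_night(apply_filters(g$series)))
  m <- grid_matrix(grid)
  expect_equal(nrow(m), length(unique(grid$vwc_lo)))
  expect_equal(ncol(m), length(unique(grid$rha_lo)))
  expect_equal(sum(!is.na(m)), sum(grid$n_total > 0))
})
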