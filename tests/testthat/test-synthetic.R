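test_that("generation is deterministic in the seed", {
  a <- generate_site(synth_config(n_days = 30, seed = 4))
  b <- generate_site(synth_config(n_days = 30, seed = 4))
  c <- generate_site(synth_config(n_days = 30, seed = 5))
  expect_identical(a$series$records, b$series$records)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$series$records$le, c$series$records$le))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_site(synth_config(n_days = 5))); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated series respect physical ranges and cadence", {
  g <- generate_site(synth_config(n_days = 60, seed = 8))
  r <- g$series$records
  expect_true(all(r$rha >= 0 & r$rha <= 100))
  expect_true(all(r$vwc > 0 & r$vwc <= synth_config()$vwc_wet))
  expect_true(all(r$le_qc == 0))
  expect_equal(nrow(r), 60 * 48)
  expect_equal(sum(r$night), 60 * 20)        # fixed 10-h night window
  # reconstructed humidity is self-consistent with VPD and Ta
  expect_equal(r$rha, rha_from_vpd(r$vpd, r$ta), tolerance = 1e-12)
})

test_that("without noise, downward night flux implies dry-side conditions", {
  g <- generate_site(synth_config(n_days = 60, seed = 12, night_noise_sd = 0,
                                  dew_rha_thresh = 101))
  r <- g$series$records
  neg_night <- r$night & r$le < 0
  expect_gt(sum(neg_night), 0)
  expect_true(all(is_sva_possible(g$template, r$rha[neg_night],
                                  r$vwc[neg_night])))
  # and ground truth marks exactly the adsorbing night half hours
  expect_true(all(g$truth$adsorption[neg_night]))
})

test_that("rain pulses are recorded and removed by the rain-day filter", {
  cfg <- synth_config(n_days = 60, seed = 14, rain_prob_per_day = 0.3)
  g <- generate_site(cfg)
  s <- apply_filters(g$series)
  r <- s$records
  rain_days <- unique(as.Date(r$timestamp[r$precip > 0]))
  expect_gt(length(rain_days), 0)
  for (d in rain_days) {
    expect_equal(sum(as.Date(r$timestamp) == d & !r$valid), 48)
  }
  expect_true(all(r$valid[!(as.Date(r$timestamp) %in% rain_days)]))
})

test_that("null sites share meteorology but carry no night signal", {
  cfg <- synth_config(n_days = 90, seed = 16)
  sva <- generate_site(cfg)
  nul <- generate_null_site(cfg)
  expect_identical(sva$series$records$ta, nul$series$records$ta)
  expect_identical(sva$series$records$vpd, nul$series$records$vpd)
  expect_identical(sva$series$records$vwc, nul$series$records$vwc)
  expect_false(any(nul$truth$adsorption))
  # daytime flux identical; nighttime differs where a gradient signal exists
  day <- !sva$series$records$night
  expect_identical(sva$series$records$le[day], nul$series$records$le[day])

  # binned night fractions hover around one half
  grid <- classify_bins(assign_bins(select_night(apply_filters(nul$series))))
  big <- grid[grid$n_total >= 20, ]
  ci_half <- qnorm(0.995) * sqrt(0.25 / big$n_total)
  outside <- abs(big$fraction_negative - 0.5) > ci_half
  expect_lt(mean(outside), 0.05)
})

test_that("tower decoupling attenuates detection monotonically", {
  cfg <- synth_config(n_days = 90, seed = 18)
  tw0 <- generate_twin_towers(cfg, decoupling = 0)
  expect_identical(tw0$short$series$records, tw0$tall$series$records)

  tw1 <- generate_twin_towers(cfg, decoupling = 1)
  nul <- generate_null_site(cfg)
  expect_identical(tw1$tall$series$records$le[tw1$tall$series$records$night],
                   nul$series$records$le[nul$series$records$night])

  sva_days <- function(site) {
    s <- apply_filters(site$series)
    fit <- fit_site(classify_bins(assign_bins(select_night(s))), default_lib)
    sum(summarize_days(label_tp(s, fit$best_template), s)$is_sva_day)
  }
  tw <- generate_twin_towers(cfg, decoupling = 0.8)
  expect_lte(sva_days(tw$tall), sva_days(tw$short))
  expect_error(generate_twin_towers(cfg, decoupling = 1.5), "decoupling")
})

test_that("configuration sanity checks reject impossible settings", {
  expect_error(synth_config(vwc_residual = 30, vwc_wet = 20), "vwc_residual")
  expect_error(synth_config(night_noise_sd = -1), "noise")
  expect_error(synth_config(rain_prob_per_day = 2), "rain")
  expect_error(synth_config(n_days = 0), "positive")
  # laplace noise family is accepted and symmetric around zero
  g <- generate_null_site(synth_config(n_days = 60, seed = 20,
                                       noise_family = "laplace"))
  night_le <- g$series$records$le[g$series$records$night]
  expect_lt(abs(mean(night_le > 0) - 0.5), 0.05)
})
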