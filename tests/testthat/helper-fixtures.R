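# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except files the tests write themselves.

# A hand-built site: n_days of 48 half hours, all fields valid unless
# overridden afterwards. Flux defaults to +10 W m-2 (upward).
make_series <- function(n_days = 2, site_id = "TST",
                        start = as.POSIXct("2021-06-01 00:00", tz = "UTC")) {
  n <- n_days * 48
  hod <- rep(seq(0, 23.5, by = 0.5), n_days)
  data.frame(timestamp = start + seq(0, by = 1800, length.out = n),
             le = rep(10, n), le_qc = 0L, vpd = 1, ta = 20, vwc = 15,
             precip = 0, night = hod >= 21 | hod < 7)
}

as_site <- function(records, site_id = "TST", meta = list()) {
  records$rha <- rha_from_vpd(records$vpd, records$ta)
  site_series(site_id, records, meta)
}

# Series whose records sit at chosen (rha, vwc, negative?) cell clusters:
# `cells` is a data.frame with columns rha, vwc, n, n_neg. VPD is derived so
# the reader-style rha is exact.
make_cluster_series <- function(cells, site_id = "CLUST") {
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    k <- cells$n[i]
    data.frame(rha = rep(cells$rha[i], k), vwc = rep(cells$vwc[i], k),
               le = c(rep(-5, cells$n_neg[i]), rep(5, k - cells$n_neg[i])))
  }))
  n <- nrow(rows)
  ta <- 20
  vpd <- esat_magnus(ta) * (1 - rows$rha / 100)
  rec <- data.frame(timestamp = as.POSIXct("2021-06-01 00:00", tz = "UTC") +
                      seq(0, by = 1800, length.out = n),
                    le = rows$le, le_qc = 0L, vpd = vpd, ta = ta,
                    vwc = rows$vwc, precip = 0, night = TRUE)
  s <- as_site(rec, site_id)
  apply_filters(s, min_ta = 5)
}

# independent brute-force binning recount (half-open [lo, hi); top RHa cell
# absorbs 100 exactly)
brute_count <- function(records, rha_lo, rha_hi, vwc_lo, vwc_hi, top_rha) {
  inr <- records$rha >= rha_lo & (records$rha < rha_hi |
                                    (top_rha & records$rha == rha_hi))
  inv <- records$vwc >= vwc_lo & records$vwc < vwc_hi
  sel <- inr & inv
  c(n = as.numeric(sum(sel)), neg = as.numeric(sum(sel & records$le < 0)))
}

default_lib <- template_library()
lib_values <- vapply(default_lib, function(t) t$vwc_rh80, numeric(1))
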