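# Shared fixture builders: tiny in-code series so no test needs stored data.

mk_ts <- function(n, start = "2020-01-01 00:00:00") {
  seq(as.POSIXct(start, tz = "UTC"), by = 1800, length.out = n)
}

mk_dendro <- function(values, start = "2020-01-01 00:00:00", id = "t01") {
  dendro_series(mk_ts(length(values), start), values, tree_id = id)
}

mk_climate <- function(temps, start = "2020-01-01 00:00:00") {
  climate_series(mk_ts(length(temps), start), temps)
}

# A small single-season tree: one simulated year, cheap enough for unit tests.
mk_sim_tree <- function(seed = 1, years = 2020, noise = 2, ...) {
  simulate_tree(sim_params(years = years, noise_sd_um = noise, seed = seed,
                           ...),
                tree_id = "t01")
}

# growth series whose G is a smooth deterministic function of DOY only
mk_doy_growth <- function(n_days = 200, start = "2020-03-01 00:00:00") {
  ts <- mk_ts(n_days * 48L, start)
  doy <- as.integer(format(ts, "%j"))
  G <- 400 * plogis(0.08 * (doy - 170))
  growth_series(ts, G, rep(0, length(ts)), tree_id = "t01")
}
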