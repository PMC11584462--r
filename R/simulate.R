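# Synthetic dendrometer / microclimate generator.
#
# Emulates the statistical structure the pipeline assumes: multi-year
# half-hourly stem radius with a double-logistic seasonal cumulative-growth
# curve, diurnal shrink-swell (tree water deficit) cycles, sensor noise,
# technical jumps, frost episodes and configurable missing runs.

#' Simulation parameters
#'
#' Bundles everything [simulate_tree()] needs. The defaults describe a
#' temperate urban maple: ~500 um radial growth per year concentrated between
#' mid-May (day 135) and early September (day 250) - radial growth of urban
#' maple and plane starts weeks after leaf-out and ceases well before leaf
#' fall - a diurnal water-deficit cycle peaking mid-afternoon at up to
#' 60 um, and 2 um sensor noise on a half-hourly grid.
#'
#' @param years calendar years to simulate (contiguous).
#' @param amplitude_um annual cumulative growth, micrometres.
#' @param onset_doy,cessation_doy day-of-year bounds of the growing season
#'   (onset < cessation).
#' @param steepness logistic steepness of the seasonal curve, 1/day.
#' @param twd_amplitude_um peak tree water deficit, micrometres.
#' @param noise_sd_um standard deviation of additive sensor noise, micrometres.
#' @param baseline_um radius at series start, micrometres.
#' @param jump_spec list of `list(at = <instant>, offset_um = <signed um>)`
#'   technical shifts; each offset applies from its instant onward.
#' @param gap_spec list of `list(at = <instant>, n = <points>)` missing runs.
#' @param frost_spec list of `list(at = <instant>, n = <points>, temp_c = <C>)`
#'   episodes during which air temperature is forced to `temp_c`.
#' @param frost_threshold_c temperatures below this define frost conditions
#'   downstream (degrees Celsius).
#' @param species,environment,area_m2,dbh_cm,height_m tree metadata passed to
#'   [tree_meta()].
#' @param seed integer; together with the tree id it fully determines the
#'   output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(years = 2019:2023,
                       amplitude_um = 500,
                       onset_doy = 135,
                       cessation_doy = 250,
                       steepness = 0.1,
                       twd_amplitude_um = 60,
                       noise_sd_um = 2,
                       baseline_um = 5000,
                       jump_spec = list(),
                       gap_spec = list(),
                       frost_spec = list(),
                       frost_threshold_c = 5,
                       species = "maple",
                       environment = "urban",
                       area_m2 = 50,
                       dbh_cm = 35,
                       height_m = 15,
                       seed = 1L) {
  stopifnot(onset_doy < cessation_doy, amplitude_um >= 0, noise_sd_um >= 0,
            steepness > 0, twd_amplitude_um >= 0, length(years) >= 1)
  p <- list(years = sort(as.integer(years)), amplitude_um = amplitude_um,
            onset_doy = onset_doy, cessation_doy = cessation_doy,
            steepness = steepness, twd_amplitude_um = twd_amplitude_um,
            noise_sd_um = noise_sd_um, baseline_um = baseline_um,
            jump_spec = jump_spec, gap_spec = gap_spec,
            frost_spec = frost_spec, frost_threshold_c = frost_threshold_c,
            species = species, environment = environment, area_m2 = area_m2,
            dbh_cm = dbh_cm, height_m = height_m, seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

softplus <- function(x) ifelse(x > 0, x, 0) + log1p(exp(-abs(x)))

# Unnormalized within-year cumulative curve: integral of the growth-rate bump
# sigma(k(d-a)) * sigma(-k(d-b)), in closed form via softplus differences.
curve_raw <- function(d, a, b, k) (softplus(k * (d - a)) - softplus(k * (d - b))) / k

#' Seasonal cumulative-growth curve
#'
#' Double-logistic cumulative growth: the instantaneous growth rate is the
#' product of an onset logistic and a (reversed) cessation logistic, so the
#' cumulative curve is ~0 before onset, rises strictly monotonically through
#' the season (reaching A/2 at the season midpoint), and saturates at the
#' annual amplitude A by year end. Each simulated year is normalized to start
#' at exactly `year_index * A` and end at `(year_index + 1) * A`, so
#' multi-year curves accumulate continuously across year boundaries.
#'
#' @param doy_frac fractional day of year, 0-based (0 = Jan 1 00:00).
#' @param year_index 0-based index of the year within the simulation.
#' @param params a [sim_params()] object.
#' @param year_length days in the year (365 or 366).
#' @return Cumulative growth in micrometres.
#' @export
seasonal_growth_curve <- function(doy_frac, year_index, params,
                                  year_length = 365) {
  a <- params$onset_doy; b <- params$cessation_doy; k <- params$steepness
  s0 <- curve_raw(0, a, b, k)
  sL <- curve_raw(year_length, a, b, k)
  within <- (curve_raw(doy_frac, a, b, k) - s0) / (sL - s0)
  params$amplitude_um * (year_index + within)
}

sim_grid <- function(years) {
  time_grid(as.POSIXct(sprintf("%d-01-01 00:00:00", years[1]), tz = "UTC"),
            as.POSIXct(sprintf("%d-12-31 23:30:00", years[length(years)]),
                       tz = "UTC"))
}

year_lengths <- function(years) {
  ifelse(years %% 4 == 0 & (years %% 100 != 0 | years %% 400 == 0), 366L, 365L)
}

# deterministic G_true over a grid (multi-year accumulation)
true_growth <- function(ts, params) {
  yr <- year_of(ts)
  yi <- match(yr, params$years) - 1L
  seasonal_growth_curve(doy_frac_of(ts), yi, params,
                        year_length = year_lengths(yr))
}

# Seasonal envelope in (0, 1): ~1 mid-season, -> 0 in winter. Shapes both the
# water-deficit amplitude and the stochastic increment bump in networks.
season_factor <- function(doy, params) {
  stats::plogis(params$steepness * (doy - params$onset_doy)) *
    stats::plogis(-params$steepness * (doy - params$cessation_doy))
}

# Diurnal deficit: zero through the night (21:00-09:00), peak mid-afternoon.
true_twd <- function(ts, params) {
  h <- hour_of(ts)
  w <- pmax(0, sin(2 * pi * (h - 9) / 24))
  params$twd_amplitude_um * season_factor(doy_frac_of(ts), params) * w
}

sim_climate <- function(ts, params, rng_offset = 1L, tree_key = "tree") {
  doy <- doy_frac_of(ts); h <- hour_of(ts)
  seasonal <- 10.8 - 9.5 * cos(2 * pi * (doy - 15) / 365)
  diurnal <- 4 * sin(2 * pi * (h - 9) / 24)
  noise <- with_seed(derive_seed(params$seed + rng_offset, tree_key),
                     stats::rnorm(length(ts), 0, 0.8))
  temp <- seasonal + diurnal + noise
  for (ep in params$frost_spec) {
    i0 <- match(as.numeric(as_utc(ep$at)), as.numeric(ts))
    if (is.na(i0)) stop("frost episode start not on the grid", call. = FALSE)
    temp[i0:min(length(ts), i0 + ep$n - 1L)] <- ep$temp_c
  }
  rh <- pmin(100, pmax(5, 100 - 2.2 * (temp - 10) +
                         with_seed(derive_seed(params$seed + rng_offset + 7L,
                                               tree_key),
                                   stats::rnorm(length(ts), 0, 3))))
  climate_series(ts, temp, rh)
}

apply_jumps_gaps <- function(radius, ts, params) {
  for (j in params$jump_spec) {
    i0 <- match(as.numeric(as_utc(j$at)), as.numeric(ts))
    if (is.na(i0)) stop("jump instant not on the grid", call. = FALSE)
    radius[i0:length(radius)] <- radius[i0:length(radius)] + j$offset_um
  }
  if (length(params$gap_spec)) {
    covered <- integer(0)
    for (g in params$gap_spec) {
      if (is.null(g$at) || is.null(g$n))
        stop("gap_spec entries need 'at' and 'n'", call. = FALSE)
      i0 <- match(as.numeric(as_utc(g$at)), as.numeric(ts))
      if (is.na(i0)) stop("gap start not on the grid", call. = FALSE)
      idx <- i0:min(length(radius), i0 + g$n - 1L)
      if (length(intersect(idx, covered)))
        stop("overlapping gap runs in gap_spec", call. = FALSE)
      covered <- c(covered, idx)
      radius[idx] <- NA_real_
    }
  }
  radius
}

#' Simulate one dendrometer-equipped tree
#'
#' Builds `radius = baseline + G_true - TWD_true + noise`, then adds jump
#' offsets cumulatively from each jump instant onward, then blanks the
#' configured gap runs. Returns the noise-free, gap-free truth alongside the
#' degraded observation so downstream stages can be scored against it.
#'
#' @param params a [sim_params()] object.
#' @param tree_id tree identifier; also seeds the tree's private RNG stream,
#'   so adding trees to a simulation never perturbs existing ones.
#' @return A list with elements `dendro` ([dendro_series()]), `truth`
#'   ([growth_series()] holding `G_true`/`TWD_true` with no missingness),
#'   `climate` ([climate_series()]) and `meta` ([tree_meta()]).
#' @examples
#' tr <- simulate_tree(sim_params(years = 2020, seed = 1), tree_id = "m01")
#' tr$dendro
#' @export
simulate_tree <- function(params, tree_id = "tree01") {
  ts <- sim_grid(params$years)
  G <- true_growth(ts, params)
  TWD <- true_twd(ts, params)
  noise <- if (params$noise_sd_um > 0)
    with_seed(derive_seed(params$seed, tree_id),
              stats::rnorm(length(ts), 0, params$noise_sd_um))
  else 0
  radius <- params$baseline_um + G - TWD + noise
  radius <- apply_jumps_gaps(radius, ts, params)
  list(dendro = dendro_series(ts, radius, tree_id = tree_id),
       truth = growth_series(ts, G, TWD, tree_id = tree_id),
       climate = sim_climate(ts, params, tree_key = tree_id),
       meta = tree_meta(tree_id, params$species, params$environment,
                        params$area_m2, params$dbh_cm, params$height_m))
}

#' Simulate a network of co-varying trees
#'
#' Generates `n_trees` trees whose cumulative-growth increments blend a shared
#' stochastic seasonal signal (weight `rho`) with tree-specific independent
#' signals (weight `1 - rho`): increments are
#' `A_i * rate(t) * (rho * e0(t) + (1 - rho) * e_i(t))` with `rate` the
#' normalized seasonal bump and `e` i.i.d. gamma multipliers (mean 1), giving
#' monotone, step-like growth. `rho = 1` yields identical growth shapes up to
#' amplitude; `rho = 0` yields near-uncorrelated increments. With
#' `n_trees = 1` the deterministic [simulate_tree()] is returned unchanged.
#'
#' @param n_trees number of trees (>= 1).
#' @param rho inter-tree co-variance weight in \[0, 1\].
#' @param params_base a [sim_params()] shared by all trees; per-tree
#'   amplitudes vary by +/-20% around `amplitude_um` (rho = 1 keeps shapes
#'   identical up to that amplitude).
#' @param amplitude_jitter relative spread of per-tree amplitudes (0 disables).
#' @param gamma_shape shape of the gamma increment multipliers; smaller values
#'   give noisier, more step-like individual growth.
#' @return A list of tree bundles as returned by [simulate_tree()], named by
#'   tree id (`t01`, `t02`, ...).
#' @export
simulate_network <- function(n_trees, rho, params_base,
                             amplitude_jitter = 0.2, gamma_shape = 0.25) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  ids <- sprintf("t%02d", seq_len(n_trees))
  if (n_trees == 1L) {
    out <- list(simulate_tree(params_base, tree_id = ids[1]))
    names(out) <- ids
    return(out)
  }
  ts <- sim_grid(params_base$years)
  n <- length(ts)
  # normalized seasonal increment bump: sums to 1 within each year
  bump <- season_factor(doy_frac_of(ts), params_base)
  yr <- year_of(ts)
  bump <- bump / ave(bump, yr, FUN = sum)
  e0 <- with_seed(derive_seed(params_base$seed, "network-common"),
                  stats::rgamma(n, shape = gamma_shape, scale = 1 / gamma_shape))
  out <- vector("list", n_trees)
  names(out) <- ids
  for (i in seq_len(n_trees)) {
    s_i <- derive_seed(params_base$seed, ids[i])
    draws <- with_seed(s_i, list(
      amp = stats::runif(1, 1 - amplitude_jitter, 1 + amplitude_jitter),
      site = stats::runif(3, 0.5, 1.5),  # per-tree area / dbh / height spread
      e = stats::rgamma(n, shape = gamma_shape, scale = 1 / gamma_shape),
      noise = stats::rnorm(n, 0, params_base$noise_sd_um)))
    A_i <- params_base$amplitude_um * draws$amp
    inc <- A_i * bump * (rho * e0 + (1 - rho) * draws$e)
    G <- cumsum(inc)
    TWD <- true_twd(ts, params_base)
    radius <- params_base$baseline_um + G - TWD +
      (if (params_base$noise_sd_um > 0) draws$noise else 0)
    radius <- apply_jumps_gaps(radius, ts, params_base)
    out[[i]] <- list(
      dendro = dendro_series(ts, radius, tree_id = ids[i]),
      truth = growth_series(ts, G, TWD, tree_id = ids[i]),
      climate = sim_climate(ts, params_base, tree_key = ids[i]),
      meta = tree_meta(ids[i], params_base$species, params_base$environment,
                       min(144, params_base$area_m2 * draws$site[1]),
                       params_base$dbh_cm * draws$site[2],
                       params_base$height_m * draws$site[3]))
  }
  out
}
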