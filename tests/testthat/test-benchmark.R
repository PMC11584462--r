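# Artificial-gap windows, benchmark table, permutation importance, and the
# nonparametric tests against brute-force oracles.

# -- gap windows --------------------------------------------------------------

test_that("artificial gap windows have the fixed seasonal dates", {
  w <- make_artificial_gaps(2019:2023)
  expect_equal(nrow(w), 15L)
  expect_equal(sum(w$period == "start"), 5L)
  w20 <- w[w$year == 2020 & w$period == "start", ]
  expect_equal(w20$first_day, as.Date("2020-04-16"))
  expect_equal(w20$last_day, as.Date("2020-05-15"))
  expect_equal(nrow(make_artificial_gaps(2021)), 3L)
  # every window spans 30 consecutive days
  expect_true(all(as.integer(w$last_day - w$first_day) + 1L == 30L))
  # start window 2020 covers exactly 1440 half-hour slots
  ts <- seq(as.POSIXct("2020-01-01", tz = "UTC"),
            as.POSIXct("2020-12-31 23:30", tz = "UTC"), by = 1800)
  idx <- dendrogap:::window_indices(ts, w20)
  expect_length(idx, 1440L)
  expect_error(make_artificial_gaps(integer(0)), "non-empty")
})

# -- benchmark table ----------------------------------------------------------

test_that("benchmark scores methods against withheld truth and counts fits", {
  tr <- mk_sim_tree(seed = 31)
  g <- zero_growth(tr$dendro)
  ds <- list(t1 = list(growth = g, truth = g, meta = tr$meta))
  oracle <- function(growth, gap_idx)
    data.frame(timestamp = growth$timestamp[gap_idx],
               G_um = g$G_um[gap_idx], flag = "ml_fill")
  tab <- run_benchmark(ds, methods = c("oracle", "spline"),
                       windows = make_artificial_gaps(2020), seed = 1,
                       custom = list(oracle = oracle))
  expect_equal(nrow(tab), 6L)  # 1 dataset x 3 windows x 2 methods
  expect_equal(attr(tab, "n_models_fit"), 0L)  # no ML method requested
  orc <- tab[tab$method == "oracle", ]
  expect_true(all(orc$applicable))
  expect_equal(orc$rmse, rep(0, 3))  # oracle returns the withheld truth
  expect_true(all(tab$n_gap_points == 1440L))
  spl <- tab[tab$method == "spline", ]
  expect_true(all(spl$rmse > 0))
})

test_that("windows outside the dataset span are marked not applicable", {
  tr <- mk_sim_tree(seed = 32)
  g <- zero_growth(tr$dendro)
  ds <- list(t1 = list(growth = g, truth = g, meta = tr$meta))
  tab <- run_benchmark(ds, methods = "spline",
                       windows = make_artificial_gaps(1999), seed = 1)
  expect_true(all(!tab$applicable))
  expect_true(all(is.na(tab$rmse)))
})

test_that("ML benchmark rows retrain without seeing the withheld window", {
  tr <- simulate_tree(sim_params(years = 2019:2020, seed = 33), "t01")
  g <- zero_growth(tr$dendro)
  ds <- list(t1 = list(growth = g, truth = g, meta = tr$meta))
  w <- make_artificial_gaps(2020)[1, , drop = FALSE]
  tab <- run_benchmark(ds, methods = "xgb", windows = w, seed = 2)
  expect_equal(attr(tab, "n_models_fit"), 1L)
  expect_true(tab$applicable)
  expect_lt(tab$rmse, 0.2 * max(g$G_um, na.rm = TRUE))
  # determinism of the whole harness
  tab2 <- run_benchmark(ds, methods = "xgb", windows = w, seed = 2)
  expect_equal(tab$rmse, tab2$rmse, tolerance = 1e-12)
})

# -- permutation feature importance -------------------------------------------

test_that("PFI ranks DOY first when growth depends on DOY only", {
  g <- mk_doy_growth(200)
  fm <- add_random_feature(build_features(g), seed = 3)
  fit <- fit_gapfill(fm, seed = 3)
  obs <- fm[!fm$gap_mask, ]
  res <- permutation_importance(fit, obs[, fit$features], obs$y, boot = 20,
                                seed = 3)
  expect_equal(nrow(res$samples), 20L)
  expect_equal(colnames(res$samples), fit$features)
  expect_equal(names(res$pfi)[1], "doy")
  # permuting an unused column costs nothing
  expect_lt(abs(res$pfi[["random"]]), 0.01)
  expect_gt(res$pfi[["doy"]], 10 * abs(res$pfi[["random"]]))
  expect_error(permutation_importance(fit, obs[, fit$features], obs$y,
                                      boot = 0), "boot")
})

test_that("PFI exceeds 1 when permuted models drop to negative R2", {
  g <- mk_doy_growth(200)
  fm <- build_features(g)
  fit <- fit_gapfill(fm, seed = 4)
  obs <- fm[!fm$gap_mask, ]
  res <- permutation_importance(fit, obs[, fit$features], obs$y, boot = 10,
                                seed = 4)
  expect_gt(res$pfi[["doy"]], 1)
})

# -- nonparametric tests vs oracles -------------------------------------------

test_that("Mann-Whitney U agrees with exhaustive enumeration on small samples", {
  cases <- list(list(a = c(1, 2, 3), b = c(10, 11, 12)),
                list(a = c(1.5, 7.1, 3.3, 9), b = c(2.2, 8.4)),
                list(a = c(5, 1), b = c(2, 3, 4, 6, 7, 8)),
                list(a = rnorm(5), b = rnorm(5)))
  set.seed(99)
  for (cs in cases) {
    got <- mann_whitney_u(cs$a, cs$b)
    want <- mwu_oracle(cs$a, cs$b)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
  # fully separated samples: U = 0 and exact two-sided p = 0.1
  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1)
  # swapping the samples reflects U and keeps p
  sw <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sw$U, 9)
  expect_equal(sw$p_value, sep$p_value)
  # identical samples (ties): U = n^2 / 2 under the approximation path
  idn <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idn$U, 4.5)
  expect_gt(idn$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Friedman statistic and exact p agree with brute-force enumeration", {
  # all cells equal -> statistic 0
  expect_equal(friedman_rmse(matrix(1, 3, 4))$statistic, 0)
  # perfect identical ordering, k = 3, n = 5 -> closed-form statistic 10
  m <- matrix(rep(c(1, 2, 3), 5), nrow = 3)
  expect_equal(friedman_rmse(m)$statistic, 10)
  set.seed(7)
  for (dims in list(c(3, 2), c(3, 3), c(4, 2))) {
    mm <- matrix(rnorm(prod(dims)), nrow = dims[1])
    got <- friedman_rmse(mm, exact = TRUE)
    want <- friedman_oracle(mm)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$p_exact, want$p_exact, tolerance = 1e-12)
  }
  expect_error(friedman_rmse(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)), "missing")
  expect_error(friedman_rmse(matrix(1:4, 2, 2)), ">= 3 methods")
})
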