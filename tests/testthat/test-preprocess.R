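# QC: temperature screening, jump detection/correction with the frost guard,
# and the 24-point linear-interpolation rule for short gaps.

test_that("temperature screening removes range violations and lone spikes", {
  cl <- mk_climate(rep(10, 20))
  expect_equal(screen_temperature(cl)$temp_c, cl$temp_c)  # all in range

  spike <- mk_climate(c(rep(10, 5), 99, rep(10, 5)))
  out <- screen_temperature(spike)
  expect_true(is.na(out$temp_c[6]))
  expect_equal(out$qc[6], "removed")
  expect_false(anyNA(out$temp_c[-6]))

  ramp <- mk_climate(seq(0, 10, by = 0.2))
  expect_equal(screen_temperature(ramp)$temp_c, ramp$temp_c)

  cold <- mk_climate(c(rep(10, 5), -80, rep(10, 5)))
  expect_true(is.na(screen_temperature(cold)$temp_c[6]))
})

test_that("jump detection finds injected steps at the right index", {
  p <- sim_params(years = 2020, noise_sd_um = 1, seed = 4,
                  jump_spec = list(list(at = "2020-06-15 00:00:00",
                                        offset_um = 500)))
  tr <- simulate_tree(p)
  ev <- detect_jumps(tr$dendro, tr$climate)
  expect_equal(nrow(ev), 1L)
  expect_equal(tr$dendro$timestamp[ev$index],
               as.POSIXct("2020-06-15 00:00:00", tz = "UTC"))
  expect_equal(ev$offset_um, 500, tolerance = 0.05)
  expect_false(ev$frost_guarded)

  clean <- simulate_tree(sim_params(years = 2020, noise_sd_um = 1, seed = 4))
  expect_equal(nrow(detect_jumps(clean$dendro, clean$climate)), 0L)
})

test_that("detection achieves exact recall and no false positives across seeds", {
  for (seed in 1:5) {
    at <- sprintf("2020-%02d-10 00:00:00", 3 + seed)
    p <- sim_params(years = 2020, noise_sd_um = 1, seed = seed,
                    jump_spec = list(list(at = at, offset_um = 10 * 1 * 25)))
    tr <- simulate_tree(p)
    ev <- detect_jumps(tr$dendro, tr$climate)
    expect_equal(nrow(ev), 1L)
    expect_equal(tr$dendro$timestamp[ev$index], as.POSIXct(at, tz = "UTC"))
  }
})

test_that("negative steps during frost are guarded and never corrected", {
  p <- sim_params(years = 2020, noise_sd_um = 1, seed = 9,
                  jump_spec = list(list(at = "2020-01-20 00:00:00",
                                        offset_um = -300)),
                  frost_spec = list(list(at = "2020-01-19 00:00:00",
                                         n = 96, temp_c = -10)))
  tr <- simulate_tree(p)
  ev <- detect_jumps(tr$dendro, tr$climate)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$frost_guarded)
  corrected <- correct_jumps(tr$dendro, ev)
  expect_equal(corrected$radius_um, tr$dendro$radius_um)  # identity
})

test_that("jump correction restores the jump-free series within noise", {
  p0 <- sim_params(years = 2020, noise_sd_um = 1, seed = 6)
  p1 <- sim_params(years = 2020, noise_sd_um = 1, seed = 6,
                   jump_spec = list(list(at = "2020-06-15 00:00:00",
                                         offset_um = 500)))
  truth <- simulate_tree(p0)$dendro
  jumped <- simulate_tree(p1)$dendro
  ev <- detect_jumps(jumped, simulate_tree(p1)$climate)
  fixed <- correct_jumps(jumped, ev)
  # offset estimate includes one step of sensor noise; level error stays small
  expect_lt(max(abs(fixed$radius_um - truth$radius_um)), 5 * 1)
  # first differences preserved everywhere except at the corrected index
  d_before <- diff(jumped$radius_um)
  d_after <- diff(fixed$radius_um)
  expect_equal(d_after[-(ev$index - 1L)], d_before[-(ev$index - 1L)])
  # no-events correction is the identity
  expect_equal(correct_jumps(jumped, ev[0, , drop = FALSE]), jumped)
})

test_that("jump detection demands enough data and alignment", {
  short <- mk_dendro(c(1:5, NA, NA, NA, NA, NA))
  expect_error(detect_jumps(short, NULL), "10 non-missing")
  s <- mk_dendro(rnorm(50, 100))
  expect_warning(detect_jumps(s, NULL), "frost guard disabled")
  cl <- mk_climate(rep(10, 40))
  expect_error(detect_jumps(s, cl), "not aligned")
})

test_that("short-gap filling follows the 24-point rule exactly", {
  # run of 2 missing between 0 and 3 -> linear 1, 2
  s <- mk_dendro(c(0, NA, NA, 3, 4))
  f <- fill_short_gaps(s)
  expect_equal(f$radius_um, c(0, 1, 2, 3, 4))
  expect_equal(f$flag[2:3], c("linear_fill", "linear_fill"))

  # run of exactly 24 is filled; run of 25 is untouched
  v24 <- c(0, rep(NA, 24), 25)
  f24 <- fill_short_gaps(mk_dendro(v24))
  expect_equal(f24$radius_um, 0:25)
  v25 <- c(0, rep(NA, 25), 26)
  f25 <- fill_short_gaps(mk_dendro(v25))
  expect_equal(sum(is.na(f25$radius_um)), 25L)

  # runs touching the series ends stay missing
  edge <- fill_short_gaps(mk_dendro(c(NA, NA, 3, NA, 5, NA)))
  expect_equal(is.na(edge$radius_um), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(edge$radius_um[4], 4)
})

test_that("filling never alters observed values and never loses data", {
  tr <- mk_sim_tree(seed = 3,
                    gap_spec = list(list(at = "2020-05-01 00:00:00", n = 10),
                                    list(at = "2020-08-01 00:00:00", n = 30)))
  f <- fill_short_gaps(tr$dendro)
  obs <- !is.na(tr$dendro$radius_um)
  expect_equal(f$radius_um[obs], tr$dendro$radius_um[obs])
  expect_gte(sum(!is.na(f$radius_um)), sum(obs))
  expect_equal(sum(is.na(f$radius_um)), 30L)  # only the long run remains
})
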