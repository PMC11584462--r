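# Splitting, normalization, model training/evaluation, CV, tuning,
# gap prediction and plausibility checks.

test_that("stratified split divides each stratum at the training fraction", {
  X <- data.frame(year = rep(2019:2023, each = 20),
                  hour = rep(c(0, 6, 12, 18), times = 25))
  X <- X[order(X$year), ]
  sp <- stratified_split(X, train_frac = 0.8, seed = 1)
  expect_equal(length(sp$train), 80L)
  expect_equal(length(sp$test), 20L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(100))
  # per-stratum count is within one row of 80%
  strata <- interaction(X$year, X$hour)
  for (lev in levels(strata)) {
    rows <- which(strata == lev)
    n_tr <- length(intersect(rows, sp$train))
    expect_lte(abs(n_tr - 0.8 * length(rows)), 1)
  }
  expect_identical(sp, stratified_split(X, train_frac = 0.8, seed = 1))
  expect_false(identical(sp$train,
                         stratified_split(X, train_frac = 0.8,
                                          seed = 2)$train))
})

test_that("singleton strata go to training with a warning", {
  X <- data.frame(year = c(2019, 2019, 2019, 2019, 2020),
                  hour = c(0, 0, 0, 0, 12))
  expect_warning(sp <- stratified_split(X, seed = 1), "size 1")
  expect_true(5L %in% sp$train)
})

test_that("z-normalization uses training parameters everywhere", {
  norm <- fit_normalizer(data.frame(a = c(1, 2, 3)))
  za <- apply_normalizer(data.frame(a = c(1, 2, 3)), norm)
  expect_equal(mean(za), 0, tolerance = 1e-10)
  expect_equal(sd(za), 1, tolerance = 1e-10)
  # a shifted test column keeps its nonzero mean in transformed space
  zt <- apply_normalizer(data.frame(a = c(11, 12, 13)), norm)
  expect_equal(mean(zt), 10, tolerance = 1e-10)
  expect_error(fit_normalizer(data.frame(a = c(1, 2), b = c(3, 3))),
               "zero-variance column.*b")
})

test_that("training-only normalization is verifiable on a fitted pipeline", {
  g <- mk_doy_growth(120)
  fm <- build_features(g)
  fit <- fit_gapfill(fm, seed = 5)
  obs <- fm[!fm$gap_mask, ]
  sp <- stratified_split(obs, keys = intersect(c("year", "hour"),
                                               names(obs)), seed = 5)
  recomputed <- fit_normalizer(obs[sp$train, attr(fm, "features")])
  expect_equal(fit$norm$mean, recomputed$mean)
  expect_equal(fit$norm$sd, recomputed$sd)
  # and they differ from all-rows statistics (no leakage by construction)
  all_rows <- fit_normalizer(obs[, attr(fm, "features")])
  expect_false(isTRUE(all.equal(fit$norm$mean, all_rows$mean)))
})

test_that("boosted trees fit a smooth seasonal signal almost exactly", {
  g <- mk_doy_growth(200)
  fm <- build_features(g)
  fit <- fit_gapfill(fm, algorithm = "xgb", seed = 3)
  expect_lt(fit$rmse_train, 0.01 * diff(range(fm$y)))
  expect_lt(fit$rmse_test, 0.01 * diff(range(fm$y)))
  expect_gt(fit$adj_r2_test, 0.999)
})

test_that("nonlinear xgb beats ridge on a nonlinear seasonal label", {
  g <- mk_doy_growth(200)
  fm <- build_features(g)
  fit_xgb <- fit_gapfill(fm, algorithm = "xgb", seed = 3)
  fit_ridge <- fit_gapfill(fm, algorithm = "ridge", seed = 3)
  expect_gt(fit_ridge$rmse_test, fit_xgb$rmse_test)
})

test_that("all registered algorithms train, predict and are deterministic", {
  g <- mk_doy_growth(40)
  fm <- build_features(g)
  fm <- fm[seq(1, nrow(fm), by = 4), ]  # thin for speed
  expect_equal(attr(fm, "features"), c("doy", "hour"))  # subset keeps attrs
  for (alg in c("xgb", "rf", "knn", "ridge")) {
    f1 <- fit_gapfill(fm, algorithm = alg, seed = 11)
    f2 <- fit_gapfill(fm, algorithm = alg, seed = 11)
    expect_equal(f1$rmse_test, f2$rmse_test, tolerance = 1e-12,
                 label = paste(alg, "determinism"))
    expect_true(is.finite(f1$rmse_test), label = alg)
  }
  expect_error(train_model(matrix(1:10, 5), 1:5, algorithm = "bogus"),
               "unknown algorithm")
})

test_that("evaluation metrics match closed-form arithmetic", {
  fake <- structure(list(algorithm = "identity", p = 1), class = "fake_fit")
  # bypass the registry: evaluate via direct formulas on a hand example
  y <- c(0, 1, 2, 3, 4)
  yhat <- c(0, 1, 2, 3, 5)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  n <- 5; p <- 1
  expect_equal(sqrt(mean((y - yhat)^2)), sqrt(1 / 5))
  expect_equal(1 - (1 - r2) * (n - 1) / (n - p - 1), 1 - (1 - 0.9) * 4 / 3)
  # and through the package path with a perfect / constant predictor
  g <- mk_doy_growth(30)
  fm <- build_features(g)
  fit <- fit_gapfill(fm, algorithm = "knn", seed = 1)
  obs <- fm[!fm$gap_mask, ]
  ev_perfect <- evaluate_fit(fit, NULL, numeric(0)) |> try(silent = TRUE)
  expect_s3_class(ev_perfect, "try-error")  # empty test set refused
})

test_that("repeated cross-validation has the right shape and is reproducible", {
  g <- mk_doy_growth(20)
  fm <- build_features(g)
  X <- fm[!fm$gap_mask, attr(fm, "features")][seq(1, 900, by = 3), ]
  y <- fm$y[!fm$gap_mask][seq(1, 900, by = 3)]
  cv <- cross_validate(X, y, algorithm = "knn", k = 10, repeats = 10,
                       seed = 2)
  expect_equal(nrow(cv), 100L)
  expect_true(all(cv$rmse >= 0))
  cv2 <- cross_validate(X, y, algorithm = "knn", k = 10, repeats = 10,
                        seed = 2)
  expect_identical(cv, cv2)
  # leave-one-out: k = n, one repeat (rows spread across days)
  sp <- seq(1, 276, by = 24)
  loo <- cross_validate(X[sp, ], y[sp], algorithm = "knn", k = 12,
                        repeats = 1, seed = 1)
  expect_equal(nrow(loo), 12L)
  expect_error(cross_validate(X, y, k = 1), "k must be")
})

test_that("hyperparameter search never loses to the default candidate", {
  g <- mk_doy_growth(15)
  fm <- build_features(g)
  keep <- seq(1, nrow(fm), by = 6)
  X <- fm[keep, attr(fm, "features")]
  y <- fm$y[keep]
  tuned <- tune_model(X, y, algorithm = "ridge", iterations = 6, k = 3,
                      seed = 4)
  default_cv <- mean(cross_validate(X, y, algorithm = "ridge", k = 3,
                                    repeats = 1,
                                    seed = dendrogap:::derive_seed(4, "tune-folds"))$rmse)
  expect_lte(tuned$rmse_cv, default_cv + 1e-9)
  expect_equal(nrow(tuned$history), 6L)
  # iterations = 1 evaluates exactly the default candidate
  one <- tune_model(X, y, algorithm = "ridge", iterations = 1, k = 3,
                    seed = 4)
  expect_equal(one$rmse_cv, default_cv)
  t2 <- tune_model(X, y, algorithm = "ridge", iterations = 6, k = 3,
                   seed = 4)
  expect_identical(tuned$best_params, t2$best_params)
  expect_error(tune_model(X, y, iterations = 0), "iterations")
})

test_that("gap prediction covers every gap row and flags extrapolation", {
  tr <- mk_sim_tree(seed = 8, years = 2020,
                    gap_spec = list(list(at = "2020-06-01 00:00:00",
                                         n = 480)))
  g <- zero_growth(fill_short_gaps(tr$dendro))
  fm <- build_features(g)
  fit <- fit_gapfill(fm, seed = 8)
  seg <- predict_gaps(fit, fm)
  expect_equal(nrow(seg), 480L)
  expect_false(anyNA(seg$G_um))
  expect_true(all(seg$flag == "ml_fill"))
  expect_false(any(seg$extrapolated))  # mid-season gap is inside all ranges
  # empty gap set -> empty segment
  full <- build_features(mk_doy_growth(10))
  fit2 <- fit_gapfill(full, algorithm = "knn", seed = 1)
  expect_equal(nrow(predict_gaps(fit2, full)), 0L)
  # filling never overwrites observed values
  filled <- apply_fill(g, seg)
  obs <- !is.na(g$G_um)
  expect_equal(filled$G_um[obs], g$G_um[obs])
  expect_false(anyNA(filled$G_um))
  expect_true(all(filled$flag[!obs] == "ml_fill"))
})

test_that("sanity checks flag declines, discontinuities and negatives", {
  ts <- mk_ts(4 * 48, start = "2020-06-01 00:00:00")
  good <- data.frame(timestamp = ts, G_um = seq(100, 110, length.out = 192))
  expect_length(sanity_check(good, flank_before = 100, flank_after = 110), 0)

  dec <- data.frame(timestamp = ts,
                    G_um = c(seq(100, 110, length.out = 20),
                             seq(110, 80, length.out = 172)))
  expect_match(sanity_check(dec), "decreasing", all = FALSE)

  neg <- data.frame(timestamp = ts[1:2], G_um = c(2, -5))
  expect_match(sanity_check(neg), "negative", all = FALSE)

  jumpy <- data.frame(timestamp = ts, G_um = seq(160, 170,
                                                 length.out = 192))
  expect_match(sanity_check(jumpy, flank_before = 100), "discontinuity",
               all = FALSE)
})
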