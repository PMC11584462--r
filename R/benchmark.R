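# Evaluation harness: seasonal artificial gaps, per-method RMSE tables over
# (dataset, period, year), permutation feature importance with a random
# baseline, and nonparametric method comparison (Friedman, Mann-Whitney U).

#' Seasonal artificial gap windows
#'
#' For each year, three fixed 30-consecutive-day windows probing different
#' phases of the growing season: start (April 16 - May 15), middle
#' (June 1 - 30) and end (September 1 - 30).
#'
#' @param years integer vector of calendar years.
#' @return A data frame of class `gap_windows` with `period`, `year`,
#'   `first_day`, `last_day` (3 rows per year).
#' @export
make_artificial_gaps <- function(years) {
  if (!length(years)) stop("years must be non-empty", call. = FALSE)
  out <- do.call(rbind, lapply(as.integer(years), function(y)
    data.frame(period = c("start", "middle", "end"), year = y,
               first_day = as.Date(sprintf(c("%d-04-16", "%d-06-01",
                                             "%d-09-01"), y)),
               last_day = as.Date(sprintf(c("%d-05-15", "%d-06-30",
                                            "%d-09-30"), y)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("gap_windows", "data.frame")
  out
}

# Grid-row indices of a window within a series (empty when outside the span).
window_indices <- function(timestamps, window) {
  from <- as.POSIXct(paste(window$first_day, "00:00:00"), tz = "UTC")
  to <- as.POSIXct(paste(window$last_day, "23:30:00"), tz = "UTC")
  which(timestamps >= from & timestamps <= to)
}

blank_window <- function(growth, idx) {
  growth$G_um[idx] <- NA_real_
  growth$twd_um[idx] <- NA_real_
  growth
}

#' Run the artificial-gap benchmark
#'
#' For every dataset and every gap window: the window is blanked in all
#' member trees, each method is asked to fill it, and the fill is scored by
#' RMSE against the withheld truth on the half-hourly grid. ML methods
#' (registered algorithm ids) retrain from scratch on the data outside the
#' window (with their internal stratified train/test split), so no method
#' ever sees the withheld values; `"spline"` and `"network"` run per member
#' tree on local / reference data only and their per-tree errors are pooled.
#' A window a method cannot fill (e.g. no qualifying network reference) is
#' recorded as not applicable rather than as a failure.
#'
#' @param datasets named list; each element is a list with `growth` (a
#'   [growth_series()] or list of them for grouped datasets), `truth`
#'   (matching series with no missingness), `meta` (a [tree_meta()] table)
#'   and optionally `references` (list of [growth_series()] for
#'   `"network"`) and `thin` (integer training-grid thinning factor for ML
#'   methods, e.g. 2 to train grouped models on an hourly grid).
#' @param methods character vector of methods: registered algorithm ids
#'   (see [list_algorithms()]), `"spline"`, `"network"`, or names of entries
#'   in `custom`.
#' @param windows a [make_artificial_gaps()] table; defaults to all years
#'   spanned by the first dataset.
#' @param seed integer RNG seed.
#' @param custom named list of custom filler functions
#'   `function(growth, gap_idx)` returning a fill segment (used e.g. for
#'   oracle checks).
#' @param ml_params hyperparameter overrides for ML methods.
#' @param network_args extra arguments passed on to [network_fill()]
#'   (e.g. `cor_resolution = "daily"`).
#' @return A data frame of class `benchmark_table` with one row per
#'   (dataset, window, method): `dataset`, `period`, `year`, `method`,
#'   `rmse`, `n_gap_points`, `applicable`; attribute `n_models_fit` counts
#'   the ML models trained.
#' @export
run_benchmark <- function(datasets, methods = c("xgb", "spline"),
                          windows = NULL, seed = 1L, custom = list(),
                          ml_params = list(), network_args = list()) {
  stopifnot(length(names(datasets)) == length(datasets))
  first <- datasets[[1]]$growth
  if (inherits(first, "growth_series")) first <- list(first)
  if (is.null(windows))
    windows <- make_artificial_gaps(unique(year_of(first[[1]]$timestamp)))
  ml_ids <- intersect(methods, list_algorithms())
  rows <- list()
  n_models <- 0L
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    trees <- if (inherits(ds$growth, "growth_series")) list(ds$growth)
    else ds$growth
    truths <- if (inherits(ds$truth, "growth_series")) list(ds$truth)
    else ds$truth
    for (w in seq_len(nrow(windows))) {
      win <- windows[w, ]
      idx_list <- lapply(trees, function(g) window_indices(g$timestamp, win))
      in_span <- any(lengths(idx_list) > 0)
      truth_vals <- unlist(Map(function(tr, idx) tr$G_um[idx], truths,
                               idx_list))
      n_gap <- length(truth_vals)
      blanked <- Map(blank_window, trees, idx_list)
      for (m in methods) {
        row <- data.frame(dataset = ds_name, period = win$period,
                          year = win$year, method = m, rmse = NA_real_,
                          n_gap_points = n_gap, applicable = FALSE,
                          stringsAsFactors = FALSE)
        if (!in_span) { rows[[length(rows) + 1L]] <- row; next }
        pred <- NULL
        if (m %in% ml_ids) {
          fm <- build_features(if (length(blanked) == 1L) blanked[[1]]
                               else blanked, meta = ds$meta)
          # a dataset may declare a training-grid thinning factor (e.g. 2 to
          # train grouped models on an hourly grid); predictions always
          # cover the full half-hourly gap rows
          thin <- as.integer(ds$thin %||% 1L)
          fm_train <- fm[!fm$gap_mask, , drop = FALSE]
          if (thin > 1L)
            fm_train <- fm_train[seq(1L, nrow(fm_train), by = thin), ,
                                 drop = FALSE]
          fit <- fit_gapfill(fm_train, algorithm = m,
                             seed = derive_seed(seed,
                                                paste(ds_name, w, m)),
                             params = ml_params)
          n_models <- n_models + 1L
          seg <- predict_gaps(fit, fm)
          # score only the blanked window rows, per tree
          pred <- unlist(Map(function(g, idx) {
            k <- match(as.numeric(g$timestamp[idx]),
                       as.numeric(seg$timestamp[seg$tree_id ==
                                                  attr(g, "tree_id")]))
            seg$G_um[seg$tree_id == attr(g, "tree_id")][k]
          }, blanked, idx_list))
        } else if (m == "spline") {
          pred <- tryCatch(
            unlist(Map(function(g, idx) spline_fill(g, idx)$G_um,
                       blanked, idx_list)),
            error = function(e) NULL)
        } else if (m == "network") {
          fills <- Map(function(g, idx)
            do.call(network_fill,
                    c(list(g, ds$references %||% list(), idx),
                      network_args)), blanked, idx_list)
          if (all(vapply(fills, `[[`, logical(1), "applicable")))
            pred <- unlist(lapply(fills, function(f) f$segment$G_um))
        } else if (m %in% names(custom)) {
          pred <- unlist(Map(function(g, idx) custom[[m]](g, idx)$G_um,
                             blanked, idx_list))
        } else {
          stop("unknown method: ", m, call. = FALSE)
        }
        if (!is.null(pred) && length(pred) == n_gap && !anyNA(pred)) {
          row$rmse <- rmse(truth_vals, pred)
          row$applicable <- TRUE
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_models_fit") <- n_models
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' Permutation feature importance
#'
#' For each feature, the raw column is permuted `boot` times; after each
#' permutation the rows are re-normalized with the fit's stored training
#' parameters and re-predicted. The importance of a feature is the mean drop
#' in R2, `PFI = mean(R2_original - R2_permuted)`; values can exceed 1 when
#' permuted models have negative R2. The injected `random` feature (see
#' [add_random_feature()]) bounds "no importance": features whose PFI does
#' not exceed the random feature's carry no usable signal.
#'
#' @param fit a `dendrogap_fit` carrying normalization parameters.
#' @param X data frame of raw feature columns (conventionally the test rows;
#'   training rows may be passed instead).
#' @param y labels for those rows.
#' @param boot number of permutations per feature.
#' @param seed integer RNG seed.
#' @return A list of class `pfi_result`: `pfi` (named mean delta-R2 per
#'   feature, decreasing), `samples` (boot x features matrix of delta-R2),
#'   `r2_original`, `n_permutations`.
#' @export
permutation_importance <- function(fit, X, y, boot = 50L, seed = 1L) {
  if (boot < 1L) stop("boot must be >= 1", call. = FALSE)
  X <- as.data.frame(X)[fit$features]
  r2_orig <- r_squared(y, predict(fit, apply_normalizer(X, fit$norm)))
  samples <- matrix(NA_real_, nrow = boot, ncol = length(fit$features),
                    dimnames = list(NULL, fit$features))
  for (f in fit$features) {
    perms <- with_seed(derive_seed(seed, paste0("pfi-", f)),
                       replicate(boot, sample.int(nrow(X)),
                                 simplify = FALSE))
    for (b in seq_len(boot)) {
      Xp <- X
      Xp[[f]] <- X[[f]][perms[[b]]]
      samples[b, f] <- r2_orig -
        r_squared(y, predict(fit, apply_normalizer(Xp, fit$norm)))
    }
  }
  pfi <- sort(colMeans(samples), decreasing = TRUE)
  structure(list(pfi = pfi, samples = samples, r2_original = r2_orig,
                 n_permutations = boot), class = "pfi_result")
}

#' @export
print.pfi_result <- function(x, ...) {
  cat(sprintf("<pfi_result> %d permutations, original R2 = %.4f\n",
              x$n_permutations, x$r2_original))
  print(round(x$pfi, 4))
  invisible(x)
}

#' Friedman rank test across methods
#'
#' Classical Friedman chi-square test on within-block ranks (mean ranks for
#' ties), used to check whether gap-filling methods differ in RMSE across
#' blocks (dataset/window combinations).
#'
#' @param rmse_matrix numeric matrix, methods in rows, blocks in columns, no
#'   missing cells.
#' @param exact compute the exact permutation p-value by enumerating all
#'   within-block rank orderings (only feasible for small instances; the
#'   chi-square `p_value` is always reported as well). The chi-square
#'   approximation is anti-conservative for very few blocks, where the exact
#'   value is preferable.
#' @return A list with `statistic`, `df` and `p_value` (chi-square
#'   approximation); with `exact = TRUE` also `p_exact`.
#' @export
friedman_rmse <- function(rmse_matrix, exact = FALSE) {
  if (anyNA(rmse_matrix)) stop("missing cells", call. = FALSE)
  if (nrow(rmse_matrix) < 3L || ncol(rmse_matrix) < 2L)
    stop("need >= 3 methods and >= 2 blocks", call. = FALSE)
  ft <- stats::friedman.test(t(rmse_matrix))
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {  # fully tied blocks: no evidence of any difference
    stat <- 0
    p <- 1
  }
  out <- list(statistic = stat, df = unname(ft$parameter), p_value = p)
  if (exact) {
    k <- nrow(rmse_matrix); n <- ncol(rmse_matrix)
    perms <- all_permutations(k)
    if (nrow(perms)^n > 1e6)
      stop("instance too large for exact enumeration", call. = FALSE)
    stat_of <- function(R)  # R: k x n rank matrix
      12 * n / (k * (k + 1)) * sum((rowMeans(R) - (k + 1) / 2)^2)
    choice <- rep(1L, n)
    count <- 0L; total <- 0L
    repeat {
      total <- total + 1L
      R <- vapply(choice, function(i) perms[i, ], numeric(k))
      if (stat_of(R) >= out$statistic - 1e-9) count <- count + 1L
      j <- 1L
      while (j <= n) {
        choice[j] <- choice[j] + 1L
        if (choice[j] <= nrow(perms)) break
        choice[j] <- 1L
        j <- j + 1L
      }
      if (j > n) break
    }
    out$p_exact <- count / total
  }
  out
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Two-sided Mann-Whitney U test
#'
#' Compares two RMSE samples. The p-value is exact (by enumeration) for
#' small samples (n_a + n_b <= 12) without ties, and uses the normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @return A list with `U` (statistic for the first sample) and `p_value`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 12L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
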