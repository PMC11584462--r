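# Core gap-filling machinery: stratified train/test splitting,
# z-normalization with training-only parameters, an algorithm registry
# (gradient-boosted trees by default, plus random forest, kNN and ridge),
# early-stopped model training, evaluation, repeated cross-validation,
# sequential model-based hyperparameter search, gap prediction and
# plausibility checks on the filled values.

.algorithms <- new.env(parent = emptyenv())

#' Register a regression algorithm for gap filling
#'
#' The registry maps an algorithm id to a `fit(X, y, seed, params, control)`
#' function returning an opaque model, a `predict(model, X)` function, the
#' default hyperparameters, and a tuning space (list of
#' `list(name, type = "num"|"int", lower, upper, log = FALSE)`). Additional
#' algorithms can be plugged in without touching the package.
#'
#' @param id character algorithm id.
#' @param fit,predict fitting and prediction functions (see above).
#' @param defaults named list of default hyperparameters.
#' @param space tuning space declaration.
#' @export
register_algorithm <- function(id, fit, predict, defaults = list(),
                               space = list()) {
  assign(id, list(fit = fit, predict = predict, defaults = defaults,
                  space = space), envir = .algorithms)
  invisible(id)
}

get_algorithm <- function(id) {
  if (!exists(id, envir = .algorithms))
    stop("unknown algorithm id: ", id, call. = FALSE)
  get(id, envir = .algorithms)
}

#' List registered gap-filling algorithms
#' @return Character vector of algorithm ids.
#' @export
list_algorithms <- function() sort(ls(.algorithms))

# ---- splitting and normalization -------------------------------------------

#' Stratified train/test split
#'
#' Splits rows into training and test subsets by stratified sampling within
#' every combination of the key columns (default `year` and `hour`), so both
#' subsets are balanced across years and times of day. Within a stratum of
#' size n_s, `round(train_frac * n_s)` rows (round-half-even) go to training,
#' the rest to test; strata smaller than 5 keep at least one training row,
#' and single-row strata go to training with a warning.
#'
#' @param X data frame containing the key columns (non-gap rows only).
#' @param train_frac training fraction (default 0.8).
#' @param keys character vector of stratification columns.
#' @param seed integer RNG seed; the split is reproducible from it.
#' @return A list with integer row indices `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(X, train_frac = 0.8, keys = c("year", "hour"),
                             seed = 1L) {
  missing_keys <- setdiff(keys, names(X))
  if (length(missing_keys))
    stop("stratification key not in data: ", missing_keys[1], call. = FALSE)
  strata <- interaction(X[keys], drop = TRUE)
  groups <- split(seq_len(nrow(X)), strata)
  singletons <- 0L
  train <- with_seed(derive_seed(seed, "strat-split"), {
    picks <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      rows <- groups[[i]]
      n_s <- length(rows)
      if (n_s == 1L) {
        singletons <- singletons + 1L
        picks[[i]] <- rows
        next
      }
      n_tr <- round(train_frac * n_s)
      if (n_s < 5L) n_tr <- max(1L, n_tr)
      picks[[i]] <- rows[sample.int(n_s, min(n_tr, n_s))]
    }
    unlist(picks)
  })
  if (singletons > 0L)
    warning(sprintf("%d stratum/strata of size 1 assigned to training",
                    singletons))
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(X)), train))
}

#' Z-transformation parameters from the training subset
#'
#' Estimates per-feature mean and standard deviation on training rows only.
#' The same parameters must be used to transform the test subset and the
#' feature rows of missing periods, so no information from outside the
#' training subset leaks into normalization.
#'
#' @param X data frame or matrix of numeric feature columns (training rows).
#' @return A list of class `norm_params` with `mean` and `sd` per column.
#' @export
fit_normalizer <- function(X) {
  X <- as.data.frame(X)
  if (nrow(X) < 2L) stop("need at least 2 training rows", call. = FALSE)
  mu <- vapply(X, mean, numeric(1))
  sd <- vapply(X, stats::sd, numeric(1))
  zero <- sd == 0 | is.na(sd)
  if (any(zero))
    stop("zero-variance column cannot be normalized: ",
         names(X)[zero][1], call. = FALSE)
  structure(list(mean = mu, sd = sd, columns = names(X)),
            class = "norm_params")
}

#' Apply stored z-transformation parameters
#'
#' @param X data frame or matrix with (at least) the normalized columns.
#' @param norm a `norm_params` object from [fit_normalizer()].
#' @return A numeric matrix of the normalized columns, in stored order.
#' @export
apply_normalizer <- function(X, norm) {
  X <- as.data.frame(X)
  miss <- setdiff(norm$columns, names(X))
  if (length(miss)) stop("missing column: ", miss[1], call. = FALSE)
  out <- vapply(norm$columns,
                function(cl) (X[[cl]] - norm$mean[[cl]]) / norm$sd[[cl]],
                numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(NULL, norm$columns))
  out
}

# ---- training and evaluation -----------------------------------------------

#' Train a gap-filling regressor
#'
#' Fits the requested algorithm on normalized features. For the default
#' gradient-boosted trees (`"xgb"`), a `val_frac` share of the supplied
#' training rows is held out as a validation subset and boosting stops early
#' once validation RMSE no longer improves (patience 20 rounds), which curbs
#' overfitting without hyperparameter tuning; `early_stop = "training"`
#' monitors training RMSE instead. No tuning is performed here (see
#' [tune_model()] for the optional search).
#'
#' @param X numeric matrix/data frame of normalized features (training rows).
#' @param y numeric label (cumulative growth, micrometres).
#' @param algorithm algorithm id; see [list_algorithms()].
#' @param val_frac validation share of the training rows for early stopping.
#' @param seed integer RNG seed.
#' @param params named list of hyperparameter overrides.
#' @param early_stop `"validation"` (default) or `"training"`.
#' @return A `dendrogap_fit` with the model handle and training metrics
#'   (`rmse_train`, `adj_r2_train`, `n_train`, `p`).
#' @export
train_model <- function(X, y, algorithm = "xgb", val_frac = 0.2, seed = 1L,
                        params = list(), early_stop = c("validation",
                                                        "training")) {
  early_stop <- match.arg(early_stop)
  alg <- get_algorithm(algorithm)
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more training rows than features", call. = FALSE)
  pars <- utils::modifyList(alg$defaults, params)
  model <- alg$fit(X, y, seed = seed, params = pars,
                   control = list(val_frac = val_frac,
                                  early_stop = early_stop))
  pred <- alg$predict(model, X)
  r2 <- r_squared(y, pred)
  fit <- list(algorithm = algorithm, model = model, params = pars,
              features = colnames(X), norm = NULL, ranges = NULL,
              rmse_train = rmse(y, pred),
              adj_r2_train = adj_r_squared(r2, n, p),
              rmse_test = NA_real_, adj_r2_test = NA_real_,
              n_train = n, n_test = NA_integer_, p = p, seed = seed)
  class(fit) <- "dendrogap_fit"
  fit
}

#' @export
predict.dendrogap_fit <- function(object, newdata, ...) {
  alg <- get_algorithm(object$algorithm)
  X <- as.matrix(as.data.frame(newdata))
  storage.mode(X) <- "double"
  as.numeric(alg$predict(object$model, X[, object$features, drop = FALSE]))
}

#' @export
print.dendrogap_fit <- function(x, ...) {
  cat(sprintf(paste0("<dendrogap_fit> %s on %d features (n_train = %d)\n",
                     "  RMSE train %.4g | test %s; adj. R2 train %.4f | %s\n"),
              x$algorithm, x$p, x$n_train, x$rmse_train,
              if (is.na(x$rmse_test)) "-" else sprintf("%.4g", x$rmse_test),
              x$adj_r2_train,
              if (is.na(x$adj_r2_test)) "-" else sprintf("%.4f",
                                                         x$adj_r2_test)))
  invisible(x)
}

#' Evaluate a fitted model on a held-out subset
#'
#' Computes RMSE and adjusted R2
#' (`1 - (1 - R2) (n - 1) / (n - p - 1)` with `n` the test size and `p` the
#' number of features) on rows disjoint from training.
#'
#' @param fit a `dendrogap_fit`.
#' @param X_test normalized features of the test rows.
#' @param y_test labels of the test rows.
#' @return A list with `rmse` and `adj_r2`.
#' @export
evaluate_fit <- function(fit, X_test, y_test) {
  if (length(y_test) == 0L) stop("empty test set", call. = FALSE)
  pred <- predict(fit, X_test)
  r2 <- r_squared(y_test, pred)
  list(rmse = rmse(y_test, pred),
       adj_r2 = adj_r_squared(r2, length(y_test), fit$p))
}

#' Repeated k-fold cross-validation
#'
#' Shuffles rows into `k` folds, `repeats` times independently, fitting on
#' k-1 folds (normalization re-estimated on each training part) and scoring
#' on the held-out fold.
#'
#' @param X data frame of raw (unnormalized) feature columns.
#' @param y numeric label.
#' @param algorithm algorithm id.
#' @param k number of folds (>= 2).
#' @param repeats number of independent repetitions.
#' @param seed integer RNG seed.
#' @param params hyperparameter overrides passed to [train_model()].
#' @return A data frame with one row per (repeat, fold): `rmse`, `adj_r2`.
#' @export
cross_validate <- function(X, y, algorithm = "xgb", k = 10L, repeats = 10L,
                           seed = 1L, params = list()) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- nrow(X)
  if (n < k) stop("need at least k rows", call. = FALSE)
  rows <- vector("list", k * repeats)
  i <- 0L
  for (rep_i in seq_len(repeats)) {
    folds <- with_seed(derive_seed(seed, paste0("cv-rep", rep_i)),
                       sample(rep_len(seq_len(k), n)))
    for (fold_i in seq_len(k)) {
      tr <- which(folds != fold_i); te <- which(folds == fold_i)
      norm <- fit_normalizer(X[tr, , drop = FALSE])
      fit <- train_model(apply_normalizer(X[tr, , drop = FALSE], norm), y[tr],
                         algorithm = algorithm, params = params,
                         seed = derive_seed(seed, paste0("cv", rep_i, "-",
                                                         fold_i)))
      ev <- evaluate_fit(fit, apply_normalizer(X[te, , drop = FALSE], norm),
                         y[te])
      i <- i + 1L
      rows[[i]] <- data.frame(rep = rep_i, fold = fold_i, rmse = ev$rmse,
                              adj_r2 = ev$adj_r2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- hyperparameter search (optional path) ---------------------------------

decode_point <- function(u, space) {
  out <- list()
  for (j in seq_along(space)) {
    s <- space[[j]]
    v <- if (isTRUE(s$log)) exp(log(s$lower) + u[j] * (log(s$upper) -
                                                         log(s$lower)))
    else s$lower + u[j] * (s$upper - s$lower)
    if (s$type == "int") v <- as.integer(round(v))
    out[[s$name]] <- v
  }
  out
}

#' Sequential model-based hyperparameter search
#'
#' Optional tuning path: evaluates `iterations` hyperparameter candidates by
#' k-fold cross-validation (the folds are fixed across candidates, so
#' comparisons are paired). The first candidate is always the algorithm's
#' default setting; further initial candidates come from a Latin hypercube
#' design, after which a random-forest surrogate fitted to the evaluated
#' (parameters, CV RMSE) pairs proposes each next candidate by minimizing
#' predicted RMSE over a random pool. Returns the best candidate refitted on
#' all rows. Tuning is deliberately not part of the default pipeline: with
#' early stopping in place it typically does not improve gap-filling skill
#' and is far more expensive.
#'
#' @inheritParams cross_validate
#' @param iterations number of candidates to evaluate (>= 1).
#' @return A list with `fit` (final model trained on all rows with the best
#'   parameters; normalization from all rows), `best_params`, `rmse_cv`
#'   (best CV RMSE) and `history` (one row per candidate).
#' @export
tune_model <- function(X, y, algorithm = "xgb", iterations = 70L, k = 10L,
                       seed = 1L) {
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  alg <- get_algorithm(algorithm)
  space <- alg$space
  d <- length(space)
  if (d == 0L) stop("algorithm has no declared tuning space", call. = FALSE)
  score <- function(pars)
    mean(cross_validate(X, y, algorithm, k = k, repeats = 1L,
                        seed = derive_seed(seed, "tune-folds"),
                        params = pars)$rmse)

  n_init <- min(iterations, max(2L, ceiling(iterations / 5)))
  U <- with_seed(derive_seed(seed, "tune-lhs"),
                 lhs::randomLHS(max(n_init - 1L, 1L), d))
  cands <- list(alg$defaults[vapply(space, `[[`, "", "name")])
  if (iterations > 1L)
    for (i in seq_len(n_init - 1L)) cands[[i + 1L]] <- decode_point(U[i, ],
                                                                    space)
  evaluated <- list(); scores <- numeric(0)
  for (i in seq_len(iterations)) {
    if (i > length(cands)) {
      # surrogate proposal over a random candidate pool
      P <- do.call(rbind, lapply(evaluated, function(p)
        unlist(p[vapply(space, `[[`, "", "name")])))
      surro <- ranger::ranger(
        y = scores, x = as.data.frame(P), num.trees = 100,
        seed = derive_seed(seed, paste0("surro", i)), num.threads = 1)
      pool_u <- with_seed(derive_seed(seed, paste0("pool", i)),
                          matrix(stats::runif(200 * d), ncol = d))
      pool <- lapply(seq_len(nrow(pool_u)),
                     function(r) decode_point(pool_u[r, ], space))
      Ppool <- do.call(rbind, lapply(pool, function(p) unlist(p)))
      colnames(Ppool) <- colnames(P)
      pred <- stats::predict(surro, data = as.data.frame(Ppool))$predictions
      cands[[i]] <- pool[[which.min(pred)]]
    }
    evaluated[[i]] <- cands[[i]]
    scores[i] <- score(cands[[i]])
  }
  best <- which.min(scores)
  hist <- cbind(iteration = seq_len(iterations),
                do.call(rbind, lapply(evaluated, as.data.frame)),
                rmse_cv = scores)
  norm <- fit_normalizer(X)
  fit <- train_model(apply_normalizer(X, norm), y, algorithm = algorithm,
                     params = evaluated[[best]],
                     seed = derive_seed(seed, "tune-final"))
  fit$norm <- norm
  list(fit = fit, best_params = evaluated[[best]], rmse_cv = scores[best],
       history = hist)
}

# ---- end-to-end per-dataset fitting and gap prediction ---------------------

#' Fit a gap-filling model to a feature matrix
#'
#' Orchestrates the default pipeline on one dataset: keep non-gap rows, split
#' them into training and test subsets by stratified sampling on `year` and
#' `hour`, estimate z-normalization on the training subset only, train the
#' regressor with early stopping, and evaluate on the test subset. The
#' returned fit carries the normalization parameters and raw feature ranges
#' needed to predict missing periods.
#'
#' @param fm a [build_features()] matrix.
#' @param algorithm algorithm id (default `"xgb"`).
#' @param train_frac training fraction of the non-gap rows.
#' @param seed integer RNG seed.
#' @param params hyperparameter overrides.
#' @param early_stop see [train_model()].
#' @return A `dendrogap_fit` with train and test metrics filled in.
#' @export
fit_gapfill <- function(fm, algorithm = "xgb", train_frac = 0.8, seed = 1L,
                        params = list(),
                        early_stop = c("validation", "training")) {
  feats <- feature_cols(fm)
  obs <- fm[!fm$gap_mask, , drop = FALSE]
  keys <- intersect(c("year", "hour"), names(obs))
  split <- stratified_split(obs, train_frac = train_frac, keys = keys,
                            seed = seed)
  Xtr_raw <- obs[split$train, feats, drop = FALSE]
  norm <- fit_normalizer(Xtr_raw)
  fit <- train_model(apply_normalizer(Xtr_raw, norm), obs$y[split$train],
                     algorithm = algorithm, seed = seed, params = params,
                     early_stop = early_stop)
  fit$norm <- norm
  fit$ranges <- lapply(Xtr_raw, range)
  if (length(split$test)) {
    ev <- evaluate_fit(fit,
                       apply_normalizer(obs[split$test, feats, drop = FALSE],
                                        norm),
                       obs$y[split$test])
    fit$rmse_test <- ev$rmse
    fit$adj_r2_test <- ev$adj_r2
    fit$n_test <- length(split$test)
  }
  fit
}

#' Predict the missing periods of a feature matrix
#'
#' Transforms the gap rows with the *training* normalization parameters
#' stored in the fit and predicts the growth label for each. Gap rows whose
#' raw features fall outside the training feature ranges are still predicted
#' but marked `extrapolated`. Observed rows are never touched.
#'
#' @param fit a `dendrogap_fit` from [fit_gapfill()] (must carry `norm`).
#' @param fm the [build_features()] matrix the fit belongs to.
#' @return A data frame (one row per gap row) with `tree_id`, `timestamp`,
#'   predicted `G_um`, `flag = "ml_fill"` and `extrapolated`.
#' @export
predict_gaps <- function(fit, fm) {
  if (is.null(fit$norm))
    stop("fit carries no normalization parameters; use fit_gapfill()",
         call. = FALSE)
  gap <- fm[fm$gap_mask, , drop = FALSE]
  if (nrow(gap) == 0L)
    return(data.frame(tree_id = character(), timestamp = as_utc(character()),
                      G_um = numeric(), flag = character(),
                      extrapolated = logical()))
  pred <- predict(fit, apply_normalizer(gap[, fit$features, drop = FALSE],
                                        fit$norm))
  extra <- rep(FALSE, nrow(gap))
  if (!is.null(fit$ranges))
    for (cl in names(fit$ranges))
      extra <- extra | gap[[cl]] < fit$ranges[[cl]][1] |
        gap[[cl]] > fit$ranges[[cl]][2]
  data.frame(tree_id = gap$tree_id, timestamp = gap$timestamp, G_um = pred,
             flag = "ml_fill", extrapolated = extra,
             stringsAsFactors = FALSE)
}

#' Insert fill predictions into a growth series
#'
#' Writes predicted values into missing slots only; observed values are never
#' overwritten. The provenance flag of each filled slot is taken from the
#' segment (`ml_fill`, `spline_fill`, `network_fill`).
#'
#' @param growth a [growth_series()] with missing slots.
#' @param segment a fill segment as returned by [predict_gaps()],
#'   [spline_fill()] or [network_fill()].
#' @return The filled [growth_series()].
#' @export
apply_fill <- function(growth, segment) {
  idx <- match(as.numeric(segment$timestamp), as.numeric(growth$timestamp))
  if (anyNA(idx)) stop("segment timestamps not on the series grid",
                       call. = FALSE)
  target <- is.na(growth$G_um[idx])
  idx <- idx[target]
  growth$G_um[idx] <- segment$G_um[target]
  growth$flag[idx] <- segment$flag[target]
  growth
}

#' Plausibility checks on a filled segment
#'
#' Gap-filling models can produce physically implausible cumulative growth -
#' most notably multi-day declines; such predictions should be
#' inspected and, if confirmed erroneous, deleted in favour of another
#' method. This check reports, without modifying any data: (a) predicted
#' cumulative growth decreasing over a run longer than one day, (b) a
#' discontinuity between the fill and the flanking observations exceeding
#' `max_discontinuity_um`, and (c) negative predicted values.
#'
#' @param segment a fill segment (`timestamp`, `G_um`).
#' @param flank_before,flank_after optional numeric: last observed `G_um`
#'   before / first after the gap.
#' @param max_discontinuity_um flank mismatch tolerance, micrometres.
#' @return Character vector of warnings (empty when all checks pass).
#' @export
sanity_check <- function(segment, flank_before = NULL, flank_after = NULL,
                         max_discontinuity_um = 20) {
  out <- character(0)
  g <- segment$G_um
  if (length(g) > 1L) {
    dec <- runs_of(c(FALSE, diff(g) < 0))
    for (i in seq_len(nrow(dec))) {
      span <- as.numeric(segment$timestamp[dec$end[i]]) -
        as.numeric(segment$timestamp[dec$start[i] - 1L])
      if (span > 86400)
        out <- c(out, sprintf(
          "decreasing predicted growth over %.1f days starting %s",
          span / 86400, format(segment$timestamp[dec$start[i] - 1L])))
    }
  }
  if (!is.null(flank_before) && length(g) &&
      abs(g[1] - flank_before) > max_discontinuity_um)
    out <- c(out, sprintf("discontinuity of %.1f um at gap start",
                          abs(g[1] - flank_before)))
  if (!is.null(flank_after) && length(g) &&
      abs(g[length(g)] - flank_after) > max_discontinuity_um)
    out <- c(out, sprintf("discontinuity of %.1f um at gap end",
                          abs(g[length(g)] - flank_after)))
  if (any(g < 0))
    out <- c(out, sprintf("%d negative predicted value(s)", sum(g < 0)))
  out
}
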