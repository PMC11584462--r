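# Built-in algorithm registry entries. All fits are single-threaded and
# fully determined by (data, params, seed).

fit_xgb <- function(X, y, seed, params, control) {
  n <- nrow(X)
  val_frac <- control$val_frac %||% 0.2
  early_stop <- control$early_stop %||% "validation"
  xgb_params <- list(objective = "reg:squarederror",
                     eta = params$eta, max_depth = params$max_depth,
                     min_child_weight = params$min_child_weight,
                     subsample = params$subsample,
                     tree_method = "hist", nthread = 1,
                     seed = derive_seed(seed, "xgb"))
  if (early_stop == "validation" && n >= 10L) {
    idx_val <- with_seed(derive_seed(seed, "xgb-val"),
                         sample.int(n, max(1L, round(val_frac * n))))
    dtrain <- xgboost::xgb.DMatrix(X[-idx_val, , drop = FALSE],
                                   label = y[-idx_val])
    evals <- list(val = xgboost::xgb.DMatrix(X[idx_val, , drop = FALSE],
                                             label = y[idx_val]))
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    evals <- list(train = dtrain)
  }
  xgboost::xgb.train(params = xgb_params, data = dtrain,
                     nrounds = params$nrounds, evals = evals,
                     early_stopping_rounds = params$patience, verbose = 0)
}

fit_rf <- function(X, y, seed, params, control) {
  df <- as.data.frame(X)
  ranger::ranger(y = y, x = df, num.trees = params$num_trees,
                 mtry = min(ncol(df), max(1L, params$mtry)),
                 min.node.size = params$min_node_size,
                 seed = derive_seed(seed, "rf"), num.threads = 1)
}

fit_knn <- function(X, y, seed, params, control) {
  caret::knnreg(X, y, k = min(params$k, nrow(X)))
}

fit_ridge <- function(X, y, seed, params, control) {
  glmnet::glmnet(X, y, alpha = 0, lambda = params$lambda,
                 standardize = FALSE)
}

register_builtin_algorithms <- function() {
  register_algorithm(
    "xgb", fit = fit_xgb,
    predict = function(m, X) stats::predict(m, X),
    defaults = list(eta = 0.1, max_depth = 6L, min_child_weight = 1,
                    subsample = 1, nrounds = 300L, patience = 20L),
    space = list(list(name = "eta", type = "num", lower = 0.01, upper = 0.3,
                      log = TRUE),
                 list(name = "max_depth", type = "int", lower = 2, upper = 8),
                 list(name = "min_child_weight", type = "num", lower = 1,
                      upper = 10),
                 list(name = "subsample", type = "num", lower = 0.5,
                      upper = 1)))
  register_algorithm(
    "rf", fit = fit_rf,
    predict = function(m, X)
      stats::predict(m, data = as.data.frame(X))$predictions,
    defaults = list(num_trees = 200L, mtry = 2L, min_node_size = 5L),
    space = list(list(name = "num_trees", type = "int", lower = 100,
                      upper = 500),
                 list(name = "mtry", type = "int", lower = 1, upper = 6),
                 list(name = "min_node_size", type = "int", lower = 1,
                      upper = 20)))
  register_algorithm(
    "knn", fit = fit_knn,
    predict = function(m, X) stats::predict(m, X),
    defaults = list(k = 5L),
    space = list(list(name = "k", type = "int", lower = 2, upper = 30)))
  register_algorithm(
    "ridge", fit = fit_ridge,
    predict = function(m, X) as.numeric(stats::predict(m, X)),
    defaults = list(lambda = 0.01),
    space = list(list(name = "lambda", type = "num", lower = 1e-4, upper = 10,
                      log = TRUE)))
}

.onLoad <- function(libname, pkgname) {
  register_builtin_algorithms()
}
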