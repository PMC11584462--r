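# Predictor matrix construction (purely temporal features plus per-tree site
# constants), iterative VIF multicollinearity screening, and the random
# baseline feature used to calibrate permutation importance.

FEATURE_NAMES <- c("doy", "year", "hour", "area", "height", "random")

#' Build the predictor matrix and growth label
#'
#' Rows are aligned to the growth-series timestamps; candidate columns are
#' `doy` (day of year, 1-366), `year` (calendar year, integer), `hour`
#' (fractional hour, 0-23.5), `area` (unsealed area m2, constant per tree),
#' `height` (tree height m, constant per tree) and extra numeric columns
#' supplied via `extra`. The label `y` is cumulative growth `G_um`;
#' `gap_mask` is `TRUE` exactly where `y` is missing. With
#' `features = "auto"`, single-tree input uses `doy, year, hour` (site
#' constants carry no variance within one tree); multi-tree input adds
#' `area`, and additionally `height` when every tree is non-urban with a
#' known height. Auto mode also drops any remaining constant-variance
#' column (e.g. `year` on a single-year record), since a constant cannot be
#' z-normalized and carries no signal.
#'
#' @param growth a [growth_series()] or a list of them (grouped dataset).
#' @param meta a [tree_meta()] table covering all tree ids (required when
#'   `area` or `height` is used).
#' @param features `"auto"` or a character vector of column names.
#' @param extra optional data frame of additional numeric predictor columns,
#'   one row per output row (opt-in hook, e.g. climate covariates).
#' @return A data frame of class `feature_matrix` with columns `tree_id`,
#'   `timestamp`, the feature columns, `y` and `gap_mask`; attribute
#'   `features` names the predictor columns.
#' @export
build_features <- function(growth, meta = NULL, features = "auto",
                           extra = NULL) {
  if (inherits(growth, "growth_series")) growth <- list(growth)
  ids <- unname(vapply(growth, function(g) attr(g, "tree_id"), character(1)))
  auto <- identical(features, "auto")
  if (auto) {
    features <- c("doy", "year", "hour")
    if (length(growth) > 1L) {
      features <- c(features, "area")
      if (!is.null(meta)) {
        m <- meta[match(ids, meta$tree_id), , drop = FALSE]
        if (all(m$environment == "non-urban") && !anyNA(m$height_m))
          features <- c(features, "height")
      }
    }
  }
  unknown <- setdiff(features, FEATURE_NAMES)
  if (length(unknown))
    stop("unknown feature column: ", unknown[1], call. = FALSE)
  if (any(c("area", "height") %in% features) && is.null(meta))
    stop("meta table required for site features", call. = FALSE)

  blocks <- lapply(seq_along(growth), function(i) {
    g <- growth[[i]]
    out <- data.frame(tree_id = ids[i], timestamp = g$timestamp,
                      stringsAsFactors = FALSE)
    if ("doy" %in% features) out$doy <- doy_of(g$timestamp)
    if ("year" %in% features) out$year <- year_of(g$timestamp)
    if ("hour" %in% features) out$hour <- hour_of(g$timestamp)
    if ("area" %in% features)
      out$area <- meta$area_m2[match(ids[i], meta$tree_id)]
    if ("height" %in% features)
      out$height <- meta$height_m[match(ids[i], meta$tree_id)]
    out$y <- g$G_um
    out$gap_mask <- is.na(g$G_um)
    out
  })
  fm <- do.call(rbind, blocks)
  rownames(fm) <- NULL
  if (auto) {
    # constant columns (single-tree area/height, single-year 'year') carry no
    # signal and cannot be z-normalized: drop them in auto mode
    keep <- vapply(features, function(cl)
      stats::var(fm[[cl]][!fm$gap_mask]) > 0, logical(1))
    for (cl in features[!keep]) fm[[cl]] <- NULL
    features <- features[keep]
  }
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(fm))
    fm <- cbind(fm[setdiff(names(fm), c("y", "gap_mask"))], extra,
                fm[c("y", "gap_mask")])
    features <- c(features, names(extra))
  }
  attr(fm, "features") <- features
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

feature_cols <- function(fm) attr(fm, "features")

#' @export
`[.feature_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("y", "gap_mask") %in% names(out))) {
    attr(out, "features") <- intersect(attr(x, "features"), names(out))
    class(out) <- c("feature_matrix", "data.frame")
  }
  out
}

vif_one <- function(X, j) {
  fit <- stats::lm.fit(cbind(1, as.matrix(X[, -j, drop = FALSE])), X[[j]])
  r2 <- 1 - sum(fit$residuals^2) / sum((X[[j]] - mean(X[[j]]))^2)
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' Iterative variance-inflation-factor screening
#'
#' Computes, for every predictor column, VIF_j = 1 / (1 - R2_j) where R2_j is
#' from the ordinary-least-squares regression (with intercept) of column j on
#' all other columns. While any VIF is at or above `threshold`, the column
#' with the largest VIF is removed (ties broken by removing the
#' later-declared column). The default threshold of 5 is the conventional
#' multicollinearity cut-off for regression feature screening.
#'
#' @param X data frame or matrix of numeric predictor columns (>= 2
#'   non-constant columns, more rows than columns).
#' @param threshold VIF removal threshold.
#' @return A list with `retained` (column names kept), `dropped`, and `vif`
#'   (named vector of final VIFs, all below `threshold`).
#' @export
vif_screen <- function(X, threshold = 5) {
  X <- as.data.frame(X)
  const <- vapply(X, function(v) stats::var(v) == 0, logical(1))
  if (any(const))
    stop("constant column must be dropped before VIF screening: ",
         names(X)[const][1], call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("need more rows than columns", call. = FALSE)
  dropped <- character(0)
  repeat {
    if (ncol(X) < 2L) break
    vifs <- vapply(seq_along(X), function(j) vif_one(X, j), numeric(1))
    names(vifs) <- names(X)
    if (max(vifs) < threshold) break
    worst <- max(which(vifs == max(vifs)))  # tie: drop later column
    dropped <- c(dropped, names(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  if (ncol(X) >= 2L) {
    vifs <- vapply(seq_along(X), function(j) vif_one(X, j), numeric(1))
    names(vifs) <- names(X)
  } else {
    vifs <- stats::setNames(1, names(X))
  }
  list(retained = names(X), dropped = dropped, vif = vifs)
}

#' Append the random baseline feature
#'
#' Adds an i.i.d. uniform(0, 1) column named `random`, reproducible from
#' `seed`. Its permutation importance provides the statistical baseline for
#' "no importance": real features whose importance does not exceed the random
#' feature's carry no usable signal.
#'
#' @param fm a [build_features()] matrix.
#' @param seed integer RNG seed.
#' @return The matrix with one extra `random` feature column.
#' @export
add_random_feature <- function(fm, seed = 1L) {
  feats <- feature_cols(fm)
  vals <- with_seed(derive_seed(seed, "random-feature"),
                    stats::runif(nrow(fm)))
  pos <- match("y", names(fm))
  out <- cbind(fm[seq_len(pos - 1L)], random = vals,
               fm[pos:ncol(fm)])
  attr(out, "features") <- c(feats, "random")
  class(out) <- c("feature_matrix", "data.frame")
  out
}
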