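#' Dendrometer stem-radius series on a regular 30-min grid
#'
#' A `dendro_series` is a data frame with columns `timestamp` (POSIXct, strictly
#' increasing with a constant 30-min step), `radius_um` (stem radius in
#' micrometres, `NA` for missing grid slots) and `flag` (provenance of each
#' value: `"observed"` for never-modified measurements, or one of
#' `"linear_fill"`, `"ml_fill"`, `"spline_fill"`, `"network_fill"`,
#' `"removed"`). Gaps are always explicit `NA` slots, never skipped rows.
#'
#' @param timestamps POSIXct (or parseable character) instants on a 30-min grid.
#' @param radius_um numeric stem radius per instant, micrometres; `NA` allowed.
#' @param flag character provenance flag per instant.
#' @param tree_id identifier of the measured tree.
#' @return A data frame of class `dendro_series` with attribute `tree_id`.
#' @examples
#' ts <- seq(as.POSIXct("2020-01-01", tz = "UTC"), by = 1800, length.out = 4)
#' dendro_series(ts, c(100, 101, NA, 102), tree_id = "t1")
#' @export
dendro_series <- function(timestamps, radius_um,
                          flag = rep("observed", length(timestamps)),
                          tree_id = "tree") {
  timestamps <- as_utc(timestamps)
  check_grid(timestamps, what = "dendro_series")
  stopifnot(length(radius_um) == length(timestamps),
            length(flag) == length(timestamps))
  if (any(!is.na(radius_um) & !is.finite(radius_um)))
    stop("radius values must be finite where present", call. = FALSE)
  bad <- setdiff(unique(flag), SOURCE_FLAGS)
  if (length(bad)) stop("unknown source flag: ", bad[1], call. = FALSE)
  out <- data.frame(timestamp = timestamps, radius_um = as.numeric(radius_um),
                    flag = as.character(flag), stringsAsFactors = FALSE)
  attr(out, "tree_id") <- as.character(tree_id)
  class(out) <- c("dendro_series", "data.frame")
  out
}

#' Microclimate series (air temperature and relative humidity)
#'
#' Same 30-min grid conventions as [dendro_series()]. Relative humidity must
#' lie in \[0, 100\] where present.
#'
#' @param timestamps POSIXct instants on a 30-min grid.
#' @param temp_c air temperature, degrees Celsius; `NA` allowed.
#' @param rh_pct relative humidity, percent in \[0, 100\]; `NA` allowed.
#' @param qc character QC flag per instant (`"ok"` or `"removed"`).
#' @return A data frame of class `climate_series`.
#' @export
climate_series <- function(timestamps, temp_c,
                           rh_pct = rep(NA_real_, length(timestamps)),
                           qc = rep("ok", length(timestamps))) {
  timestamps <- as_utc(timestamps)
  check_grid(timestamps, what = "climate_series")
  stopifnot(length(temp_c) == length(timestamps),
            length(rh_pct) == length(timestamps))
  if (any(!is.na(rh_pct) & (rh_pct < 0 | rh_pct > 100)))
    stop("rh_pct outside [0, 100]", call. = FALSE)
  out <- data.frame(timestamp = timestamps, temp_c = as.numeric(temp_c),
                    rh_pct = as.numeric(rh_pct), qc = as.character(qc),
                    stringsAsFactors = FALSE)
  class(out) <- c("climate_series", "data.frame")
  out
}

#' Zero-growth model output: cumulative growth and tree water deficit
#'
#' Holds, per 30-min grid slot, cumulative growth `G_um` (non-decreasing over
#' non-missing points, micrometres since series start) and tree water deficit
#' `twd_um` (>= 0), plus a QC flag (`"ok"`, `"winter_corrected"`,
#' `"negative_removed"`) and the provenance `flag` shared with
#' [dendro_series()].
#'
#' @param timestamps POSIXct instants on a 30-min grid.
#' @param G_um cumulative growth, micrometres; `NA` on gap slots.
#' @param twd_um tree water deficit, micrometres; `NA` on gap slots.
#' @param qc character QC flag per instant.
#' @param flag character provenance flag per instant (see [dendro_series()]).
#' @param tree_id identifier of the measured tree.
#' @return A data frame of class `growth_series` with attribute `tree_id`.
#' @export
growth_series <- function(timestamps, G_um, twd_um,
                          qc = rep("ok", length(timestamps)),
                          flag = rep("observed", length(timestamps)),
                          tree_id = "tree") {
  timestamps <- as_utc(timestamps)
  check_grid(timestamps, what = "growth_series")
  stopifnot(length(G_um) == length(timestamps),
            length(twd_um) == length(timestamps))
  # the zero-growth invariant applies to measured growth; model-filled slots
  # (ml/spline/network) may decrease - sanity_check() reports those
  meas <- !is.na(G_um) & flag %in% c("observed", "linear_fill")
  g <- G_um[meas]
  if (length(g) > 1L && any(diff(g) < -1e-9))
    stop("G must be non-decreasing over non-missing points", call. = FALSE)
  if (any(twd_um < -1e-9, na.rm = TRUE))
    stop("TWD must be non-negative", call. = FALSE)
  out <- data.frame(timestamp = timestamps, G_um = as.numeric(G_um),
                    twd_um = as.numeric(twd_um), qc = as.character(qc),
                    flag = as.character(flag), stringsAsFactors = FALSE)
  attr(out, "tree_id") <- as.character(tree_id)
  class(out) <- c("growth_series", "data.frame")
  out
}

#' Per-tree metadata table
#'
#' @param tree_id character tree identifiers.
#' @param species `"maple"` or `"plane"`.
#' @param environment `"urban"` or `"non-urban"`.
#' @param area_m2 unsealed soil area around the tree, m2; values above the
#'   144 m2 cap (fully unsealed surroundings) are truncated to 144.
#' @param dbh_cm diameter at breast height, cm.
#' @param height_m tree height, metres; optional (`NA` allowed).
#' @return A data frame of class `tree_meta`.
#' @export
tree_meta <- function(tree_id, species, environment, area_m2, dbh_cm,
                      height_m = NA_real_) {
  species <- match.arg(species, c("maple", "plane"), several.ok = TRUE)
  environment <- match.arg(environment, c("urban", "non-urban"),
                           several.ok = TRUE)
  if (any(area_m2 <= 0)) stop("unsealed area must be positive", call. = FALSE)
  area_m2 <- pmin(area_m2, 144)
  out <- data.frame(tree_id = as.character(tree_id), species = species,
                    environment = environment, area_m2 = as.numeric(area_m2),
                    dbh_cm = as.numeric(dbh_cm),
                    height_m = as.numeric(height_m), stringsAsFactors = FALSE)
  class(out) <- c("tree_meta", "data.frame")
  out
}

#' @export
print.dendro_series <- function(x, ...) {
  cat(sprintf("<dendro_series> tree %s: %d slots (%s .. %s), %d missing\n",
              attr(x, "tree_id"), nrow(x),
              format(x$timestamp[1]), format(x$timestamp[nrow(x)]),
              sum(is.na(x$radius_um))))
  invisible(x)
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("<growth_series> tree %s: %d slots, G %.1f..%.1f um, %d missing\n",
              attr(x, "tree_id"), nrow(x),
              suppressWarnings(min(x$G_um, na.rm = TRUE)),
              suppressWarnings(max(x$G_um, na.rm = TRUE)),
              sum(is.na(x$G_um))))
  invisible(x)
}
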