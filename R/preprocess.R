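# Quality control of raw dendrometer and temperature data: plausibility
# screening of air temperature, jump (sensor shift) detection and correction
# with a frost guard, and linear interpolation of short missing runs.

#' Plausibility screening of air temperature
#'
#' Sets to missing (and flags `"removed"`) any temperature outside
#' \[`tmin`, `tmax`\] and any isolated spike whose absolute difference to
#' *both* neighbours exceeds `max_step_c`. Relative humidity is untouched.
#'
#' @param climate a [climate_series()].
#' @param tmin,tmax plausible temperature range, degrees Celsius.
#' @param max_step_c maximum plausible change per 30-min step, degrees Celsius.
#' @return The screened [climate_series()].
#' @export
screen_temperature <- function(climate, tmin = -40, tmax = 50,
                               max_step_c = 10) {
  t <- climate$temp_c
  bad <- !is.na(t) & (t < tmin | t > tmax)
  d_prev <- c(NA, abs(diff(t)))
  d_next <- c(abs(diff(t)), NA)
  spike <- !is.na(d_prev) & !is.na(d_next) &
    d_prev > max_step_c & d_next > max_step_c
  bad <- bad | (spike & !is.na(t))
  climate$temp_c[bad] <- NA_real_
  climate$qc[bad] <- "removed"
  climate
}

#' Detect technical jumps in a stem-radius series
#'
#' A jump is a first difference whose absolute value exceeds
#' `diff_threshold_mad` times the MAD of all first differences of the series.
#' When an aligned temperature record is supplied, flagged *negative*
#' differences coinciding with air temperature at or below `frost_temp_c` are
#' marked `frost_guarded`: frost-induced stem shrinkage must not be treated
#' as a sensor failure and is never corrected.
#'
#' @param series a [dendro_series()].
#' @param climate an aligned [climate_series()], or `NULL` to disable the
#'   frost guard (a warning is emitted).
#' @param diff_threshold_mad detection threshold as a multiple of the MAD of
#'   first differences.
#' @param frost_temp_c frost guard temperature, degrees Celsius.
#' @return A data frame of class `jump_events` with columns `index` (grid
#'   position of the first post-jump value), `offset_um` (signed step size)
#'   and `frost_guarded`.
#' @export
detect_jumps <- function(series, climate = NULL, diff_threshold_mad = 10,
                         frost_temp_c = 5) {
  r <- series$radius_um
  if (sum(!is.na(r)) < 10L)
    stop("need at least 10 non-missing points to detect jumps", call. = FALSE)
  if (is.null(climate)) {
    warning("no climate series supplied: frost guard disabled")
  } else if (nrow(climate) != nrow(series) ||
             !isTRUE(all.equal(as.numeric(climate$timestamp),
                               as.numeric(series$timestamp)))) {
    stop("climate series is not aligned with the dendrometer series",
         call. = FALSE)
  }
  d <- diff(r)  # NA across missing slots: jumps at gap edges are undetectable
  ok <- !is.na(d)
  scale <- stats::mad(d[ok])
  if (scale == 0) scale <- max(stats::sd(d[ok]), .Machine$double.eps)
  hit <- which(ok & abs(d) > diff_threshold_mad * scale)
  frost <- rep(FALSE, length(hit))
  if (!is.null(climate) && length(hit)) {
    temp <- climate$temp_c[hit + 1L]
    frost <- d[hit] < 0 & !is.na(temp) & temp <= frost_temp_c
  }
  out <- data.frame(index = hit + 1L, offset_um = d[hit],
                    frost_guarded = frost)
  class(out) <- c("jump_events", "data.frame")
  out
}

#' Correct detected jumps
#'
#' For each event not explained by frost, the jump offset is subtracted from
#' every value at and after the event index, restoring level continuity.
#' Frost-guarded events are left untouched. `mode = "remove"` instead blanks
#' (flags `"removed"`) the segment from each non-frost event to the next
#' event or the series end - an aggressive alternative for data where level
#' adjustment is not trusted.
#'
#' @param series the [dendro_series()] the events were detected on.
#' @param events a `jump_events` table from [detect_jumps()].
#' @param mode `"subtract"` (default) or `"remove"`.
#' @return The corrected [dendro_series()].
#' @export
correct_jumps <- function(series, events, mode = c("subtract", "remove")) {
  mode <- match.arg(mode)
  n <- nrow(series)
  if (nrow(events) == 0L) return(series)
  if (any(events$index < 2L | events$index > n))
    stop("jump event index out of range", call. = FALSE)
  ev <- events[!events$frost_guarded, , drop = FALSE]
  if (mode == "subtract") {
    for (i in seq_len(nrow(ev))) {
      idx <- ev$index[i]:n
      series$radius_um[idx] <- series$radius_um[idx] - ev$offset_um[i]
    }
  } else {
    bounds <- c(sort(events$index), n + 1L)
    for (i in seq_len(nrow(ev))) {
      to <- min(bounds[bounds > ev$index[i]]) - 1L
      idx <- ev$index[i]:to
      series$radius_um[idx] <- NA_real_
      series$flag[idx] <- "removed"
    }
  }
  series
}

#' Linearly interpolate short missing runs
#'
#' Every maximal missing run of at most `max_points` consecutive grid slots
#' (default 24 points = 12 h) that has observed values on both flanks is
#' replaced by the straight line between the flanking values and flagged
#' `"linear_fill"`. Longer runs, and runs touching either end of the series,
#' are left missing. Observed values are never altered.
#'
#' @param series a [dendro_series()] (a [growth_series()] also works; its
#'   `G_um` column is filled).
#' @param max_points longest run, in grid points, eligible for linear filling.
#' @return The filled series.
#' @export
fill_short_gaps <- function(series, max_points = 24L) {
  col <- if (inherits(series, "growth_series")) "G_um" else "radius_um"
  v <- series[[col]]
  n <- length(v)
  gaps <- runs_of(is.na(v))
  for (i in seq_len(nrow(gaps))) {
    s <- gaps$start[i]; e <- gaps$end[i]
    if (gaps$length[i] > max_points || s == 1L || e == n) next
    left <- v[s - 1L]; right <- v[e + 1L]
    if (is.na(left) || is.na(right)) next
    w <- seq_len(gaps$length[i]) / (gaps$length[i] + 1L)
    v[s:e] <- left + w * (right - left)
    series$flag[s:e] <- "linear_fill"
  }
  series[[col]] <- v
  series
}
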