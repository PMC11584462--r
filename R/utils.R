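# Internal helpers shared across modules.

GRID_STEP_S <- 1800L  # 30-min measurement interval, in seconds

SOURCE_FLAGS <- c("observed", "linear_fill", "ml_fill", "spline_fill",
                  "network_fill", "removed")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 31-bit sub-seed from a base seed and a string key, so each
# tree (or other unit) gets its own reproducible stream and adding units
# never perturbs existing ones.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

# Strictly regular 30-min grid between two instants (inclusive).
time_grid <- function(from, to, step = GRID_STEP_S) {
  from <- as_utc(from); to <- as_utc(to)
  if (to < from) stop("grid end precedes start", call. = FALSE)
  seq(from, to, by = step)
}

check_grid <- function(timestamps, step = GRID_STEP_S, what = "series") {
  if (length(timestamps) == 0L) return(invisible(TRUE))
  d <- diff(as.numeric(timestamps))
  if (any(d <= 0)) stop(sprintf("%s timestamps are not strictly increasing", what),
                        call. = FALSE)
  if (any(d != step))
    stop(sprintf("%s is not on a regular %d-min grid (gaps must be explicit NA slots)",
                 what, step %/% 60L), call. = FALSE)
  invisible(TRUE)
}

doy_of <- function(timestamps) as.integer(format(timestamps, "%j"))
year_of <- function(timestamps) as.integer(format(timestamps, "%Y"))
hour_of <- function(timestamps) {
  as.integer(format(timestamps, "%H")) + as.integer(format(timestamps, "%M")) / 60
}
# fractional day-of-year (0-based within the day) for continuous curves
doy_frac_of <- function(timestamps) (doy_of(timestamps) - 1L) + hour_of(timestamps) / 24

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

adj_r_squared <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

# maximal runs of TRUE in a logical vector -> data.frame(start, end, length)
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}
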