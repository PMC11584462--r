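# Zero-growth model: partition a cleaned stem-radius series into irreversible
# cumulative growth (G) and reversible tree water deficit (TWD), plus the
# winter-artifact correction applied before model fitting.

#' Zero-growth model extraction
#'
#' Under the zero-growth model the stem grows only when the radius exceeds
#' its previous maximum. With `M(t)` the running maximum of the radius over
#' non-missing points up to `t`:
#' \deqn{G(t) = M(t) - radius(t_0), \quad TWD(t) = M(t) - radius(t)}
#' so that `radius(t) = radius(t_0) + G(t) - TWD(t)` holds exactly at every
#' non-missing point. Missing radius slots yield missing `G` and `TWD`
#' (they are not interpolated here).
#'
#' @param series a cleaned [dendro_series()] whose first value is non-missing.
#' @return A [growth_series()] with `G_um` non-decreasing and `twd_um >= 0`.
#' @examples
#' ts <- seq(as.POSIXct("2020-01-01", tz = "UTC"), by = 1800, length.out = 4)
#' zero_growth(dendro_series(ts, c(100, 101, 100.5, 102)))
#' @export
zero_growth <- function(series) {
  r <- series$radius_um
  if (all(is.na(r))) stop("all-missing series", call. = FALSE)
  if (is.na(r[1]))
    stop("first value must be non-missing (trim leading gaps first)",
         call. = FALSE)
  ok <- !is.na(r)
  M <- rep(NA_real_, length(r))
  M[ok] <- cummax(r[ok])
  growth_series(series$timestamp, G_um = M - r[1], twd_um = M - r,
                flag = series$flag, tree_id = attr(series, "tree_id"))
}

#' Winter-artifact correction of a growth series
#'
#' The zero-growth model does not account for winter bark-cell degradation
#' and frost shrink/swell, which can register as spurious growth outside the
#' growing season. This correction (a) sets negative `G` values to missing
#' (flag `negative_removed`), and (b) cancels positive growth increments that
#' occur before `start_doy` or after `end_doy` of each year: `G` is held at
#' its prior value across such increments (flag `winter_corrected`), keeping
#' the series non-decreasing. With `action = "remove"`, offending winter rows
#' are instead set missing entirely.
#'
#' @param growth a [growth_series()].
#' @param start_doy,end_doy day-of-year bounds outside which growth increments
#'   are considered artifacts (defaults: before day 60 and after day 304).
#' @param action `"cancel"` (default) or `"remove"`.
#' @return The corrected [growth_series()].
#' @export
winter_correction <- function(growth, start_doy = 60L, end_doy = 304L,
                              action = c("cancel", "remove")) {
  action <- match.arg(action)
  G <- growth$G_um
  neg <- !is.na(G) & G < 0
  G[neg] <- NA_real_
  growth$twd_um[neg] <- NA_real_
  growth$qc[neg] <- "negative_removed"

  doy <- doy_of(growth$timestamp)
  winter <- doy < start_doy | doy > end_doy
  ok <- which(!is.na(G))
  if (length(ok) > 1L) {
    inc <- diff(G[ok])  # increment attributed to the later timestamp
    bad <- inc > 0 & winter[ok[-1L]]
    if (action == "cancel") {
      # subtract the running sum of cancelled winter increments
      adj <- c(0, cumsum(inc * bad))
      G[ok] <- G[ok] - adj
      growth$qc[ok[-1L][bad]] <- "winter_corrected"
    } else {
      drop_idx <- ok[-1L][bad]
      G[drop_idx] <- NA_real_
      growth$twd_um[drop_idx] <- NA_real_
      growth$qc[drop_idx] <- "winter_corrected"
    }
  }
  growth$G_um <- G
  growth
}
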