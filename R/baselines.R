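# Reference gap fillers the ML approach is compared against: local cubic
# smoothing-spline interpolation across the gap, and linear-regression
# network interpolation from a highly co-varying neighbouring tree.

#' Cubic-spline gap filling
#'
#' Fits a natural cubic interpolating spline through daily means of
#' `anchor_days` of observed values on each flank of the gap and evaluates it
#' on the gap timestamps (daily averaging suppresses half-hourly sensor noise
#' in the anchors, as is conventional for dendrometer interpolation). When
#' the flanking data are exactly linear, the spline reproduces the straight
#' line. Because the gap interior is governed by the flank derivatives, the
#' spline can - and should be allowed to - undershoot and produce decreasing
#' cumulative-growth segments, e.g. when rapid season-onset growth starts
#' just beyond the gap; such artefacts are surfaced by [sanity_check()], not
#' suppressed here.
#'
#' @param growth a [growth_series()] with the gap present as missing slots.
#' @param gap_idx integer row indices of the gap (a maximal missing run).
#' @param anchor_days days of flanking observations used on each side.
#' @return A fill segment data frame (`timestamp`, `G_um`,
#'   `flag = "spline_fill"`).
#' @export
spline_fill <- function(growth, gap_idx, anchor_days = 5) {
  if (length(gap_idx) == 0L)
    return(data.frame(timestamp = as_utc(character()), G_um = numeric(),
                      flag = character()))
  gap_idx <- sort(gap_idx)
  n <- nrow(growth)
  span <- as.integer(anchor_days * 86400 / GRID_STEP_S)
  left <- max(1L, gap_idx[1] - span):(gap_idx[1] - 1L)
  right <- (gap_idx[length(gap_idx)] + 1L):min(n, gap_idx[length(gap_idx)] +
                                                 span)
  if (gap_idx[1] == 1L || all(is.na(growth$G_um[left])))
    stop("left flank has no observations: cannot spline-fill", call. = FALSE)
  if (gap_idx[length(gap_idx)] == n || all(is.na(growth$G_um[right])))
    stop("right flank has no observations: cannot spline-fill", call. = FALSE)
  anchor <- c(left, right)
  anchor <- anchor[!is.na(growth$G_um[anchor])]
  # daily-mean anchors: one (time, G) knot per calendar day and flank
  day <- format(growth$timestamp[anchor], "%Y-%m-%d")
  x <- as.numeric(tapply(as.numeric(growth$timestamp[anchor]), day, mean))
  y <- as.numeric(tapply(growth$G_um[anchor], day, mean))
  o <- order(x)
  x <- x[o]; y <- y[o]
  xg <- as.numeric(growth$timestamp[gap_idx])
  pred <- if (length(x) >= 4L)
    stats::spline(x, y, xout = xg, method = "natural")$y
  else stats::approx(x, y, xout = xg, rule = 2)$y
  data.frame(timestamp = growth$timestamp[gap_idx], G_um = pred,
             flag = "spline_fill", stringsAsFactors = FALSE)
}

#' Network interpolation from a co-varying neighbouring tree
#'
#' Assumes neighbouring trees of one species and site share stem-growth
#' variability: the reference tree whose growth *increments* correlate best
#' with the target's over their common non-missing span is selected (it must
#' have no missing values inside the gap window and its increment correlation
#' must reach `min_r`; cumulative levels of any two growing trees correlate
#' trivially, so shared variability is judged on first differences), the
#' target is regressed on it by ordinary least squares on levels (intercept
#' included), and the regression predicts the gap. When no reference qualifies the result is
#' *not applicable* - a distinct outcome, not an error, and a common one in
#' practice since references tend to have gaps of their own. With
#' `combine = "average"`, predictions from all qualifying references are
#' averaged instead of using only the best one.
#'
#' @param target a [growth_series()] with the gap present as missing slots.
#' @param references list of candidate reference [growth_series()] on the
#'   same grid span.
#' @param gap_idx integer row indices of the gap.
#' @param min_r minimum Pearson increment correlation for a reference to
#'   qualify.
#' @param combine `"best"` (default) or `"average"`.
#' @param cor_resolution scale on which the increment-correlation gate is
#'   computed: `"native"` (half-hourly, default) or `"daily"` (correlation
#'   of daily growth totals). Half-hourly increments of extracted growth are
#'   sparse spike trains, so for field-style records the daily gate is the
#'   practical choice - applicability is then typically limited by reference
#'   completeness rather than by correlation.
#' @return A list of class `network_fill`: `applicable` (logical); when
#'   applicable, `segment` (fill data frame flagged `"network_fill"`),
#'   `reference` (chosen tree id(s)), `r` (correlation(s)); otherwise
#'   `reason`.
#' @export
network_fill <- function(target, references, gap_idx, min_r = 0.5,
                         combine = c("best", "average"),
                         cor_resolution = c("native", "daily")) {
  combine <- match.arg(combine)
  cor_resolution <- match.arg(cor_resolution)
  if (inherits(references, "growth_series")) references <- list(references)
  cand <- list()
  for (ref in references) {
    if (nrow(ref) != nrow(target)) next
    if (any(is.na(ref$G_um[gap_idx]))) next  # must cover the gap completely
    both <- !is.na(target$G_um) & !is.na(ref$G_um)
    both[gap_idx] <- FALSE
    if (sum(both) < 10L) next
    # co-variance gate on increments over consecutive jointly observed slots
    idx <- which(both)
    if (cor_resolution == "native") {
      adj <- idx[c(diff(idx) == 1L, FALSE)]
      r <- stats::cor(target$G_um[adj + 1L] - target$G_um[adj],
                      ref$G_um[adj + 1L] - ref$G_um[adj])
    } else {
      day <- format(target$timestamp[idx], "%Y-%m-%d")
      dinc <- function(v) tapply(v, day, function(x) x[length(x)] - x[1])
      r <- stats::cor(as.numeric(dinc(target$G_um[idx])),
                      as.numeric(dinc(ref$G_um[idx])))
    }
    if (is.na(r) || r < min_r) next
    cand[[length(cand) + 1L]] <- list(ref = ref, r = r, both = both)
  }
  if (!length(cand))
    return(structure(list(applicable = FALSE,
                          reason = "no reference without gap-window missingness correlates above min_r"),
                     class = "network_fill"))
  ord <- order(vapply(cand, `[[`, numeric(1), "r"), decreasing = TRUE)
  cand <- if (combine == "best") cand[ord[1]] else cand[ord]
  preds <- vapply(cand, function(cc) {
    co <- stats::coef(stats::lm(target$G_um[cc$both] ~ cc$ref$G_um[cc$both]))
    co[1] + co[2] * cc$ref$G_um[gap_idx]
  }, numeric(length(gap_idx)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = length(gap_idx))
  structure(list(
    applicable = TRUE,
    segment = data.frame(timestamp = target$timestamp[gap_idx],
                         G_um = rowMeans(preds), flag = "network_fill",
                         stringsAsFactors = FALSE),
    reference = vapply(cand, function(cc) attr(cc$ref, "tree_id"),
                       character(1)),
    r = vapply(cand, `[[`, numeric(1), "r")),
    class = "network_fill")
}
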