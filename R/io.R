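# CSV readers/writers and grid alignment.
#
# Dialect: comma-separated, header row required, ISO-8601 timestamps,
# missing values written as empty fields. Radii are micrometres internally;
# readers convert from a declared input unit.

UNIT_TO_UM <- c(um = 1, mm = 1000, m = 1e6)

parse_timestamps <- function(x, path) {
  ts <- suppressWarnings(tryCatch(
    as_utc(as.character(x)),
    error = function(e) as.POSIXct(rep(NA_character_, length(x)),
                                   tz = "UTC")))
  if (anyNA(ts)) {
    each_ok <- vapply(as.character(x), function(v)
      !is.na(suppressWarnings(tryCatch(as_utc(v), error = function(e)
        as.POSIXct(NA_character_, tz = "UTC")))), logical(1))
    stop(sprintf("unparseable timestamp in %s: '%s'", path,
                 as.character(x)[which(!each_ok)[1]]), call. = FALSE)
  }
  dup <- duplicated(as.numeric(ts))
  if (any(dup))
    stop(sprintf("duplicate timestamp in %s: %s", path,
                 format(ts[which(dup)[1]])), call. = FALSE)
  ts
}

# Expand irregular (but grid-aligned) rows to a complete grid; absent rows
# become explicit NA slots.
regularize <- function(ts, values, step = GRID_STEP_S) {
  o <- order(ts)
  ts <- ts[o]
  grid <- time_grid(ts[1], ts[length(ts)], step)
  idx <- match(as.numeric(ts), as.numeric(grid))
  if (anyNA(idx))
    stop(sprintf("timestamp %s is not aligned to the %d-min grid",
                 format(ts[which(is.na(idx))[1]]), step %/% 60L), call. = FALSE)
  out <- lapply(values, function(v) {
    full <- rep(if (is.character(v)) NA_character_ else NA_real_, length(grid))
    full[idx] <- v[o]
    full
  })
  c(list(timestamp = grid), out)
}

#' Read a dendrometer CSV into a [dendro_series()]
#'
#' Expects columns `timestamp` and `radius_um` (or a radius column in the unit
#' named by `unit`), plus an optional `flag` column as written by
#' [write_series()]. Rows absent from the file become explicit missing grid
#' slots; rows present in the file with an empty radius field stay missing.
#'
#' @param path CSV file path.
#' @param tree_id tree identifier to attach; defaults to the file stem.
#' @param unit unit of the radius column: `"um"` (default), `"mm"` or `"m"`.
#' @param grid_step_min grid step in minutes (default 30).
#' @return A [dendro_series()].
#' @export
read_dendro_csv <- function(path, tree_id = NULL, unit = c("um", "mm", "m"),
                            grid_step_min = 30L) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df))
    stop("missing 'timestamp' column in ", path, call. = FALSE)
  vcol <- intersect(c("radius_um", paste0("radius_", unit), "radius"), names(df))
  if (!length(vcol)) stop("missing radius column in ", path, call. = FALSE)
  if (nrow(df) == 0L)
    return(dendro_series(as.POSIXct(character(), tz = "UTC"), numeric(),
                         character(), tree_id %||% basename(path)))
  ts <- parse_timestamps(df$timestamp, path)
  vals <- list(radius = as.numeric(df[[vcol[1]]]) * UNIT_TO_UM[[unit]],
               flag = if ("flag" %in% names(df)) as.character(df$flag) else NULL)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  reg <- regularize(ts, vals, step = grid_step_min * 60L)
  flag <- reg$flag %||% rep("observed", length(reg$timestamp))
  flag[is.na(flag)] <- "observed"
  dendro_series(reg$timestamp, reg$radius, flag,
                tree_id = tree_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Read a microclimate CSV into a [climate_series()]
#'
#' Expects columns `timestamp`, `temp_c` and optionally `rh_pct` and `qc`.
#'
#' @inheritParams read_dendro_csv
#' @return A [climate_series()].
#' @export
read_climate_csv <- function(path, grid_step_min = 30L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(df)))
    stop("climate CSV needs 'timestamp' and 'temp_c' columns: ", path,
         call. = FALSE)
  if (nrow(df) == 0L)
    return(climate_series(as.POSIXct(character(), tz = "UTC"), numeric()))
  ts <- parse_timestamps(df$timestamp, path)
  vals <- list(temp = as.numeric(df$temp_c),
               rh = if ("rh_pct" %in% names(df)) as.numeric(df$rh_pct) else NULL,
               qc = if ("qc" %in% names(df)) as.character(df$qc) else NULL)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  reg <- regularize(ts, vals, step = grid_step_min * 60L)
  qc <- reg$qc %||% rep("ok", length(reg$timestamp))
  qc[is.na(qc)] <- "ok"
  climate_series(reg$timestamp, reg$temp,
                 reg$rh %||% rep(NA_real_, length(reg$timestamp)), qc)
}

#' Read a growth CSV into a [growth_series()]
#'
#' Expects columns `timestamp`, `G_um`, `twd_um` and optionally `qc`, `flag`.
#'
#' @inheritParams read_dendro_csv
#' @return A [growth_series()].
#' @export
read_growth_csv <- function(path, tree_id = NULL, grid_step_min = 30L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "G_um", "twd_um")
  if (!all(need %in% names(df)))
    stop("growth CSV needs columns ", paste(need, collapse = ", "), ": ", path,
         call. = FALSE)
  if (nrow(df) == 0L)
    return(growth_series(as.POSIXct(character(), tz = "UTC"), numeric(),
                         numeric(), tree_id = tree_id %||% basename(path)))
  ts <- parse_timestamps(df$timestamp, path)
  vals <- list(G = as.numeric(df$G_um), twd = as.numeric(df$twd_um),
               qc = if ("qc" %in% names(df)) as.character(df$qc) else NULL,
               flag = if ("flag" %in% names(df)) as.character(df$flag) else NULL)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  reg <- regularize(ts, vals, step = grid_step_min * 60L)
  qc <- reg$qc %||% rep("ok", length(reg$timestamp)); qc[is.na(qc)] <- "ok"
  flag <- reg$flag %||% rep("observed", length(reg$timestamp))
  flag[is.na(flag)] <- "observed"
  growth_series(reg$timestamp, reg$G, reg$twd, qc, flag,
                tree_id = tree_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Read a tree metadata CSV
#'
#' Expects columns `tree_id,species,environment,area_m2,dbh_cm,height_m`
#' (`height_m` optional).
#'
#' @param path CSV file path.
#' @return A [tree_meta()] table.
#' @export
read_tree_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tree_meta(df$tree_id, df$species, df$environment, df$area_m2, df$dbh_cm,
            if ("height_m" %in% names(df)) df$height_m else NA_real_)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "" else
    format(v, digits = 15, scientific = FALSE, trim = TRUE), character(1))
  out
}

fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")

#' Write a series to CSV
#'
#' Writes the package CSV dialect (ISO-8601 timestamps, empty fields for
#' missing values, full double precision) so that reading the file back
#' reproduces the series exactly, including flags and missingness.
#'
#' @param x a [dendro_series()], [climate_series()], [growth_series()] or
#'   [tree_meta()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) UseMethod("write_series")

write_csv_raw <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), list(sep = ","))), con)
  invisible(path)
}

#' @export
write_series.dendro_series <- function(x, path) {
  write_csv_raw(data.frame(timestamp = fmt_ts(x$timestamp),
                           radius_um = fmt_num(x$radius_um),
                           flag = x$flag), path)
}

#' @export
write_series.climate_series <- function(x, path) {
  write_csv_raw(data.frame(timestamp = fmt_ts(x$timestamp),
                           temp_c = fmt_num(x$temp_c),
                           rh_pct = fmt_num(x$rh_pct),
                           qc = x$qc), path)
}

#' @export
write_series.growth_series <- function(x, path) {
  write_csv_raw(data.frame(timestamp = fmt_ts(x$timestamp),
                           G_um = fmt_num(x$G_um),
                           twd_um = fmt_num(x$twd_um),
                           qc = x$qc, flag = x$flag), path)
}

#' @export
write_series.tree_meta <- function(x, path) {
  write_csv_raw(data.frame(tree_id = x$tree_id, species = x$species,
                           environment = x$environment,
                           area_m2 = fmt_num(x$area_m2),
                           dbh_cm = fmt_num(x$dbh_cm),
                           height_m = fmt_num(x$height_m)), path)
}

#' Restrict two gridded series to their common time span
#'
#' @param a,b two series on the same 30-min grid convention.
#' @return A list with elements `a` and `b`, both covering exactly the
#'   overlapping span (equal length).
#' @export
align_series <- function(a, b) {
  from <- max(a$timestamp[1], b$timestamp[1])
  to <- min(a$timestamp[nrow(a)], b$timestamp[nrow(b)])
  if (to < from) stop("series spans do not overlap", call. = FALSE)
  cut1 <- function(x) {
    out <- x[x$timestamp >= from & x$timestamp <= to, , drop = FALSE]
    rownames(out) <- NULL
    cls <- class(x)
    class(out) <- cls
    attr(out, "tree_id") <- attr(x, "tree_id")
    out
  }
  list(a = cut1(a), b = cut1(b))
}
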