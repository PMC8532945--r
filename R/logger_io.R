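# Reading/writing logger CSV and per-horse-day splitting.
#
# Canonical dialect: comma-separated, ISO-8601 timestamps ("%Y-%m-%d
# %H:%M:%S", UTC column and local column), period decimal separator.
# Column-mapping via `col_map` adapts other logger export dialects.

.fix_cols <- c("horse_id", "timestamp_utc", "timestamp_local",
               "lat", "lon", "height", "speed", "step_distance")

#' Write fixes to logger CSV
#'
#' @param fixes Tibble of fixes as produced by [simulate_day()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(fixes, path) {
  out <- as.data.frame(fixes)[, .fix_cols]
  out$timestamp_utc <- format(out$timestamp_utc, "%Y-%m-%d %H:%M:%S",
                              tz = "UTC")
  out$timestamp_local <- format(out$timestamp_local, "%Y-%m-%d %H:%M:%S",
                                tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a logger CSV
#'
#' Malformed rows (unparseable timestamp or non-finite coordinates) are
#' counted and dropped, never silently ignored: the returned tibble carries
#' attributes `n_errors` and `error_lines` (1-based data-row numbers), and
#' a missing mandatory column is a format error.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's header names, e.g.
#'   `c(lat = "LATITUDE", lon = "LONGITUDE")`.
#' @param id_assignment Optional named integer vector re-mapping the file's
#'   horse ids (anonymisation map): names are ids in the file, values the
#'   ids to assign.
#' @return Tibble of fixes with error attributes.
#' @export
read_logger_csv <- function(path, col_map = NULL, id_assignment = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  names(raw) <- trimws(names(raw))
  wanted <- stats::setNames(.fix_cols, .fix_cols)
  if (!is.null(col_map)) wanted[names(col_map)] <- col_map
  missing <- setdiff(unname(wanted), names(raw))
  if (length(missing))
    stop("logger file is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  num <- function(col) suppressWarnings(as.numeric(raw[[wanted[col]]]))
  ts <- function(col) as.POSIXct(raw[[wanted[col]]], tz = "UTC",
                                 format = "%Y-%m-%d %H:%M:%S")
  parsed <- tibble::tibble(
    horse_id = suppressWarnings(as.integer(raw[[wanted["horse_id"]]])),
    timestamp_utc = ts("timestamp_utc"),
    timestamp_local = ts("timestamp_local"),
    lat = num("lat"), lon = num("lon"), height = num("height"),
    speed = num("speed"), step_distance = num("step_distance"))
  ok <- !is.na(parsed$horse_id) & !is.na(parsed$timestamp_utc) &
    !is.na(parsed$timestamp_local) & is.finite(parsed$lat) &
    is.finite(parsed$lon)
  out <- parsed[ok, ]
  if (!is.null(id_assignment))
    out$horse_id <- unname(id_assignment[as.character(out$horse_id)])
  attr(out, "n_errors") <- sum(!ok)
  attr(out, "error_lines") <- which(!ok)
  out
}

#' Split fixes into horse-days
#'
#' Partitions a fix table by horse and local calendar date. No fix is lost
#' or duplicated; within each group fixes keep their time order.
#'
#' @param fixes Tibble of fixes.
#' @return Named list of tibbles, names `"<horse_id>:<yyyy-mm-dd>"`, in
#'   horse-then-date order.
#' @export
split_horse_days <- function(fixes) {
  if (nrow(fixes) == 0) return(list())
  date <- format(fixes$timestamp_local, "%Y-%m-%d", tz = "UTC")
  key <- paste(fixes$horse_id, date, sep = ":")
  ord <- order(fixes$horse_id, fixes$timestamp_local)
  fixes <- fixes[ord, ]
  split(fixes, factor(key[ord], levels = unique(key[ord])))
}

#' Observation-day index of local timestamps
#'
#' Maps local timestamps to 1-based day indices relative to the study start
#' (the local date of the earliest fix unless `day1_date` is given).
#'
#' @param timestamp_local POSIXct vector (local clock, stored as UTC).
#' @param day1_date Optional `Date` of observation day 1.
#' @return Integer vector of day indices.
#' @export
obs_day_index <- function(timestamp_local, day1_date = NULL) {
  d <- as.Date(format(timestamp_local, "%Y-%m-%d", tz = "UTC"))
  if (is.null(day1_date)) day1_date <- min(d)
  as.integer(d - as.Date(day1_date)) + 1L
}
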