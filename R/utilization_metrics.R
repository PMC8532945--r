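# Response variables of the two analyses: distinct squares visited per hour
# per horse-day, and per-square daily usage frequency, with the 12 h
# (4320-fix) day-inclusion rule and the with/without-pasture variants.

#' Fixes required for an included day
#'
#' Twelve hours of recording at the sampling interval: `12 * 3600 /
#' fix_interval` fixes (4320 at the default 10 s interval).
#'
#' @param fix_interval Sampling interval, s.
#' @param min_hours Hours of recording required (default 12).
#' @return Integer fix count.
#' @export
min_fixes_per_day <- function(fix_interval = 10, min_hours = 12) {
  as.integer(min_hours * 3600 / fix_interval)
}

#' Day-inclusion rule
#'
#' A horse-day enters the squares-per-hour analysis only with at least 12 h
#' of data, i.e. `n_fixes >= 4320` at one fix per 10 s; the boundary is
#' inclusive (exactly 12 h qualifies). Applied separately per dataset
#' variant, so the paddock-only dataset shrinks.
#'
#' @param n_fixes Fix counts (vector).
#' @param fix_interval,min_hours See [min_fixes_per_day()].
#' @return Logical vector.
#' @export
day_inclusion <- function(n_fixes, fix_interval = 10, min_hours = 12) {
  n_fixes >= min_fixes_per_day(fix_interval, min_hours)
}

#' Distinct squares visited per hour for one horse-day
#'
#' For each clock hour with at least `hour_coverage` of its expected fixes
#' (>= 324 of 360 at the defaults), counts the distinct grid squares among
#' that hour's fixes; `squares_per_hour` is the mean over qualifying hours.
#' A square occupied in two different hours counts in each hour. The day is
#' marked not included when `n_fixes` falls below the 12 h rule.
#'
#' @param day_fixes Tibble of one horse's filtered fixes for one local day.
#' @param grid A [grid_spec()].
#' @param origin Projection origin `c(lat, lon)`.
#' @param hour_coverage Minimum fraction of an hour's expected fixes for
#'   that hour to qualify (default 0.9).
#' @param fix_interval Sampling interval, s.
#' @return One-row tibble: `horse_id`, `date`, `n_fixes`, `hours_covered`,
#'   `squares_per_hour` (NA when no hour qualifies), `included`.
#' @export
squares_per_hour <- function(day_fixes, grid, origin, hour_coverage = 0.9,
                             fix_interval = 10) {
  n <- nrow(day_fixes)
  hid <- if (n) day_fixes$horse_id[1] else NA_integer_
  date <- if (n) format(day_fixes$timestamp_local[1], "%Y-%m-%d", tz = "UTC")
          else NA_character_
  if (n == 0)
    return(tibble::tibble(horse_id = hid, date = date, n_fixes = 0L,
                          hours_covered = 0L, squares_per_hour = NA_real_,
                          included = FALSE))
  xy <- project_to_local(day_fixes$lat, day_fixes$lon, origin)
  sq <- square_of(xy$x, xy$y, grid)
  key <- square_key(sq$row, sq$col, grid)
  sec <- as.numeric(day_fixes$timestamp_local) %% 86400
  hour <- as.integer(sec %/% 3600)
  need <- hour_coverage * 3600 / fix_interval
  n_per_hour <- tabulate(hour + 1L, 24L)
  first <- !duplicated(hour * (grid$n_rows * grid$n_cols + 1) + key)
  d_per_hour <- tabulate(hour[first] + 1L, 24L)
  qual <- n_per_hour >= need
  sph <- if (any(qual)) mean(d_per_hour[qual]) else NA_real_
  tibble::tibble(horse_id = hid, date = date, n_fixes = n,
                 hours_covered = as.integer(sum(qual)),
                 squares_per_hour = sph,
                 included = day_inclusion(n, fix_interval) && any(qual))
}

#' Horse-day usage table for a dataset variant
#'
#' Splits a filtered fix table into horse-days and computes
#' [squares_per_hour()] for each; for the `"paddock_only"` variant the
#' caller should have clipped pasture fixes first (see [clip_to_areas()]),
#' so the inclusion rule is re-applied on the reduced stream.
#'
#' @param fixes Filtered fix table (all horses, all days).
#' @param layout A [farm_layout()].
#' @param grid A [grid_spec()].
#' @param variant Label stored in the result.
#' @param day1_date Optional date of observation day 1 (default: earliest).
#' @param ... Passed to [squares_per_hour()].
#' @return Tibble with one row per horse-day, including `day` index and
#'   `variant`.
#' @export
horse_day_usage <- function(fixes, layout, grid = grid_for_layout(layout),
                            variant = "with_pasture", day1_date = NULL,
                            ...) {
  groups <- split_horse_days(fixes)
  if (is.null(day1_date) && nrow(fixes))
    day1_date <- min(as.Date(format(fixes$timestamp_local, "%Y-%m-%d",
                                    tz = "UTC")))
  rows <- lapply(groups, squares_per_hour, grid = grid,
                 origin = layout$origin, ...)
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(tibble::tibble(horse_id = integer(), date = character(),
                          n_fixes = integer(), hours_covered = integer(),
                          squares_per_hour = double(), included = logical(),
                          day = integer(), variant = character()))
  out$day <- as.integer(as.Date(out$date) - as.Date(day1_date)) + 1L
  out$variant <- variant
  tibble::as_tibble(out)
}

#' Per-square daily usage frequencies
#'
#' For each local day, the percentage of that day's fixes (all horses
#' pooled) falling in each visited square:
#' `100 * n_fixes_in_square / n_fixes_that_day`. Only visited squares are
#' materialised; the visited-square universe size is reported as an
#' attribute `n_visited_squares`.
#'
#' @param fixes Filtered fix table (all horses).
#' @param grid A [grid_spec()].
#' @param layout A [farm_layout()]; supplies projection origin and the
#'   square-to-location labels.
#' @param day1_date Optional date of observation day 1.
#' @return Tibble: `day`, `date`, `row`, `col`, `n_fixes`, `frequency`
#'   (percent), `location`.
#' @export
square_frequencies <- function(fixes, grid, layout, day1_date = NULL) {
  if (nrow(fixes) == 0) stop("no fixes: frequencies undefined")
  xy <- project_to_local(fixes$lat, fixes$lon, layout$origin)
  sq <- square_of(xy$x, xy$y, grid)
  date <- format(fixes$timestamp_local, "%Y-%m-%d", tz = "UTC")
  if (is.null(day1_date)) day1_date <- min(as.Date(date))
  key <- square_key(sq$row, sq$col, grid)
  agg <- stats::aggregate(list(n_fixes = rep(1L, nrow(fixes))),
                          by = list(date = date, key = key), FUN = sum)
  day_tot <- stats::ave(agg$n_fixes, agg$date, FUN = sum)
  row <- agg$key %/% grid$n_cols
  col <- agg$key %% grid$n_cols
  out <- tibble::tibble(
    day = as.integer(as.Date(agg$date) - as.Date(day1_date)) + 1L,
    date = agg$date,
    row = as.integer(row), col = as.integer(col),
    n_fixes = agg$n_fixes,
    frequency = 100 * agg$n_fixes / day_tot,
    location = location_of(row, col, layout, grid))
  out <- out[order(out$day, out$row, out$col), ]
  attr(out, "n_visited_squares") <- length(unique(agg$key))
  out
}

#' Mean usage frequency per resource location
#'
#' For each location label, the mean of the per-square daily frequencies
#' over all (square, day) rows carrying that label — the convention under
#' which a feed stall's value is the average over its assigned squares.
#' Locations with no squares are absent from the result, not zero.
#'
#' @param frequencies Tibble from [square_frequencies()].
#' @return Tibble: `location`, `n_square_days`, `mean_frequency` (percent),
#'   ordered as [location_labels()].
#' @export
location_usage <- function(frequencies) {
  agg <- stats::aggregate(list(mean_frequency = frequencies$frequency),
                          by = list(location = frequencies$location),
                          FUN = mean)
  cnt <- table(frequencies$location)
  out <- tibble::tibble(location = agg$location,
                        n_square_days = as.integer(cnt[agg$location]),
                        mean_frequency = agg$mean_frequency)
  out[order(match(out$location, location_labels())), ]
}
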