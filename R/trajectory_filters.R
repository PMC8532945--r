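# Outlier-filter cascade for fix streams: geodetic bounding box, speed and
# step-distance limits, and paddock/pasture area clipping.

#' Remove fixes outside the farm bounding box
#'
#' Drops fixes whose latitude/longitude fall outside the most
#' northern/eastern/southern/western coordinates of the farm (the layout's
#' geodetic bounding box). Order is preserved.
#'
#' @param fixes Tibble of fixes.
#' @param layout A [farm_layout()].
#' @return List with `fixes` (retained) and `n_removed`.
#' @export
clip_bounding_box <- function(fixes, layout) {
  b <- layout$bbox
  keep <- fixes$lat >= b["min_lat"] & fixes$lat <= b["max_lat"] &
    fixes$lon >= b["min_lon"] & fixes$lon <= b["max_lon"]
  list(fixes = fixes[keep, ], n_removed = sum(!keep))
}

#' Filter physically impossible steps
#'
#' Removes a fix when its step from the previous *retained* fix of the same
#' horse implies a speed above `max_speed_kmh` or a distance above
#' `max_step_m` per `step_interval_s` (gaps scale the distance allowance
#' proportionally). Step distances are recomputed from the coordinates by
#' geodesic, not taken from the device column, so the filter stays
#' consistent with the projection used for gridding. Removal is sequential:
#' each removal keeps the previous retained fix as the anchor, so one spike
#' cannot cascade into removals of valid fixes.
#'
#' @param fixes Tibble of fixes, time-sorted per horse.
#' @param max_speed_kmh Speed limit (default 50 km/h).
#' @param max_step_m Distance limit per `step_interval_s` (default 140 m).
#' @param step_interval_s Nominal sampling interval (default 10 s).
#' @return List with `fixes`, `n_removed`, and `removed_idx` (row indices
#'   into the input).
#' @export
filter_speed_distance <- function(fixes, max_speed_kmh = 50,
                                  max_step_m = 140, step_interval_s = 10) {
  n <- nrow(fixes)
  if (n < 2) return(list(fixes = fixes, n_removed = 0L,
                         removed_idx = integer()))
  keep <- rep(TRUE, n)
  for (id in unique(fixes$horse_id)) {
    idx <- which(fixes$horse_id == id)
    if (length(idx) < 2) next
    p <- cbind(fixes$lon[idx], fixes$lat[idx])
    tt <- as.numeric(fixes$timestamp_utc[idx])
    anchor <- 1L
    for (j in 2:length(idx)) {
      d <- geosphere::distGeo(p[anchor, ], p[j, ])
      dt <- max(tt[j] - tt[anchor], 1)
      allowed <- max_step_m * dt / step_interval_s
      if (d > allowed || d / dt * 3.6 > max_speed_kmh)
        keep[idx[j]] <- FALSE
      else anchor <- j
    }
  }
  list(fixes = fixes[keep, ], n_removed = sum(!keep),
       removed_idx = which(!keep))
}

#' Clip fixes to the paddock and pasture polygons
#'
#' Removes fixes whose projected position lies outside the paddock (and,
#' when `include_pasture`, the pastures). With `include_pasture = FALSE`
#' pasture fixes are removed as well: the "paddock only" dataset variant.
#'
#' @param fixes Tibble of fixes.
#' @param layout A [farm_layout()].
#' @param include_pasture Keep fixes on pasture? Default `TRUE`.
#' @return List with `fixes` and `n_removed`.
#' @export
clip_to_areas <- function(fixes, layout, include_pasture = TRUE) {
  if (nrow(fixes) == 0) return(list(fixes = fixes, n_removed = 0L))
  xy <- project_to_local(fixes$lat, fixes$lon, layout$origin)
  keep <- point_in_poly(xy$x, xy$y, layout$paddock)
  if (include_pasture)
    for (p in layout$pastures)
      keep <- keep | point_in_poly(xy$x, xy$y, p$poly)
  list(fixes = fixes[keep, ], n_removed = sum(!keep))
}

#' Run the full filter cascade
#'
#' Order: bounding box, then speed/step-distance, then area clip. The
#' returned report satisfies removed + retained = input count.
#'
#' @inheritParams filter_speed_distance
#' @inheritParams clip_to_areas
#' @return List with `fixes` and `report` (named counts:
#'   `input`, `outside_bbox`, `speed_distance`, `outside_areas`,
#'   `retained`).
#' @export
filter_fixes <- function(fixes, layout, include_pasture = TRUE,
                         max_speed_kmh = 50, max_step_m = 140,
                         step_interval_s = 10) {
  s1 <- clip_bounding_box(fixes, layout)
  s2 <- filter_speed_distance(s1$fixes, max_speed_kmh, max_step_m,
                              step_interval_s)
  s3 <- clip_to_areas(s2$fixes, layout, include_pasture)
  list(fixes = s3$fixes,
       report = c(input = nrow(fixes),
                  outside_bbox = s1$n_removed,
                  speed_distance = s2$n_removed,
                  outside_areas = s3$n_removed,
                  retained = nrow(s3$fixes)))
}

#' Flag horse-days from damaged or mis-adjusted loggers
#'
#' Operationalises the exclusion of heavily demolished or incorrectly
#' adjusted loggers: a horse-day is flagged when the fraction of its fixes
#' removed by the cascade (plus malformed rows, if supplied) exceeds
#' `max_bad_fraction`.
#'
#' @param report_by_day Data.frame with columns `horse_id`, `date`,
#'   `n_input`, `n_removed` (and optionally `n_malformed`).
#' @param max_bad_fraction Exclusion threshold (default 0.2).
#' @return The input with logical column `excluded` added.
#' @export
flag_damaged_days <- function(report_by_day, max_bad_fraction = 0.2) {
  bad <- report_by_day$n_removed
  if (!is.null(report_by_day$n_malformed)) bad <- bad + report_by_day$n_malformed
  report_by_day$excluded <- bad / pmax(report_by_day$n_input, 1) >
    max_bad_fraction
  report_by_day
}
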