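# Farm layout, local planar projection, 3 x 3 m grid indexing and
# square-to-resource assignment.

#' Resource location labels used on the farm
#'
#' The fixed vocabulary of functional areas: seven feed stalls (`FS_1`..`FS_7`),
#' three concentrate feed stalls (`CF_1`..`CF_3`), three lying halls
#' (`LH_1`..`LH_3`), two straw racks (`RF_1`, `RF_2`), two shelters
#' (`SH_1`, `SH_2`), two drinking troughs (`TR_1`, `TR_2`), plus the two
#' catch-all areas `PADDOCK` (paddock area without resources) and `PASTURE`.
#'
#' @return Character vector of the 21 valid location labels.
#' @export
location_labels <- function() {
  c(paste0("FS_", 1:7), paste0("CF_", 1:3), paste0("LH_", 1:3),
    paste0("RF_", 1:2), paste0("SH_", 1:2), paste0("TR_", 1:2),
    "PADDOCK", "PASTURE")
}

rect_poly <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("x", "y")))
}

#' Construct a farm layout
#'
#' A farm layout holds the paddock polygon, pasture polygons with their
#' availability calendars, labelled resource-zone polygons, the geodetic
#' origin of the local planar frame, and the farm's lat/lon bounding box.
#' All polygons are in local planar metres (east = x, north = y) relative
#' to `origin`.
#'
#' @param paddock Two-column matrix of polygon vertices (m), unclosed.
#' @param pastures Named list; each element a list with `poly` (vertex
#'   matrix, m) and `open_days` (integer vector of observation-day indices
#'   on which that pasture is open).
#' @param resources Named list of vertex matrices; names must come from
#'   [location_labels()] (excluding `PADDOCK`/`PASTURE`).
#' @param origin Numeric `c(lat, lon)` in degrees: the point mapped to (0, 0).
#' @param bbox_margin_m Margin (m) added around all polygons when deriving
#'   the geodetic bounding box used by the bounding-box filter.
#' @return An object of class `farm_layout`.
#' @export
farm_layout <- function(paddock, pastures, resources, origin,
                        bbox_margin_m = 15) {
  stopifnot(is.matrix(paddock), ncol(paddock) == 2,
            is.list(pastures), is.list(resources),
            length(origin) == 2)
  bad <- setdiff(names(resources),
                 setdiff(location_labels(), c("PADDOCK", "PASTURE")))
  if (length(bad))
    stop("unknown resource labels: ", paste(bad, collapse = ", "))
  for (nm in names(resources)) {
    ctr <- colMeans(resources[[nm]])
    if (!point_in_poly(ctr[1], ctr[2], paddock))
      stop("resource zone ", nm, " does not lie inside the paddock")
  }
  all_xy <- do.call(rbind, c(list(paddock),
                             lapply(pastures, `[[`, "poly"),
                             unname(resources)))
  xr <- range(all_xy[, 1]) + c(-1, 1) * bbox_margin_m
  yr <- range(all_xy[, 2]) + c(-1, 1) * bbox_margin_m
  corners <- unproject_from_local(c(xr[1], xr[2]), c(yr[1], yr[2]), origin)
  layout <- structure(list(
    paddock = paddock,
    pastures = pastures,
    resources = resources,
    origin = c(lat = unname(origin[1]), lon = unname(origin[2])),
    bbox = c(min_lat = min(corners$lat), max_lat = max(corners$lat),
             min_lon = min(corners$lon), max_lon = max(corners$lon)),
    extent = c(min_x = xr[1], max_x = xr[2], min_y = yr[1], max_y = yr[2])
  ), class = "farm_layout")
  layout
}

#' @export
print.farm_layout <- function(x, ...) {
  cat("<farm_layout>\n")
  cat("  origin:", sprintf("%.5f N, %.5f E", x$origin["lat"], x$origin["lon"]), "\n")
  cat("  paddock vertices:", nrow(x$paddock), "\n")
  cat("  pastures:", length(x$pastures), " resources:", length(x$resources), "\n")
  invisible(x)
}

#' Example active-stable layout
#'
#' A synthetic one-hectare paddock (125 x 80 m) at 54.3 N in northern
#' Germany with the full resource complement (feed stalls, concentrate
#' stalls, lying halls, straw racks, shelters, troughs) and two adjacent
#' pasture blocks on the east side, each with its own availability
#' calendar. Geometry is invented but dimensioned realistically: lying
#' halls of 160-250 m2, feed stalls of 30-60 m2, troughs of a few m2.
#'
#' @param origin Geodetic origin `c(lat, lon)`; default 54.3 N, 9.1 E.
#' @param n_days Observation days covered by the pasture calendars.
#' @param summer_days Days (1..summer_days) on which pastures may open.
#' @return A [farm_layout()] object.
#' @export
example_layout <- function(origin = c(54.3, 9.1), n_days = 227,
                           summer_days = 159) {
  paddock <- rect_poly(0, 0, 125, 80)
  # pastures share the paddock's east edge; each open half the summer
  half <- ceiling(summer_days / 2)
  pastures <- list(
    PASTURE_A = list(poly = rect_poly(125, 0, 275, 100),
                     open_days = seq_len(min(half, summer_days)),
                     gate = c(125, 40)),
    PASTURE_B = list(poly = rect_poly(0, -110, 150, 0),
                     open_days = seq(half + 1, summer_days),
                     gate = c(60, 0))
  )
  resources <- list(
    # feed stalls along the west and north fence
    FS_1 = rect_poly(2, 2, 10, 8),    FS_2 = rect_poly(2, 12, 10, 18),
    FS_3 = rect_poly(2, 22, 10, 28),  FS_4 = rect_poly(2, 32, 10, 38),
    FS_5 = rect_poly(30, 72, 50, 78), FS_6 = rect_poly(95, 72, 105, 78),
    FS_7 = rect_poly(110, 72, 120, 78),
    CF_1 = rect_poly(2, 44, 8, 50),   CF_2 = rect_poly(2, 54, 8, 60),
    CF_3 = rect_poly(2, 64, 8, 70),
    # lying halls in the interior
    LH_1 = rect_poly(55, 5, 80, 15),   # metal hall, 250 m2
    LH_2 = rect_poly(30, 40, 46, 50),  # tarp skin, 160 m2
    LH_3 = rect_poly(60, 40, 76, 50),  # tarp skin, 160 m2
    RF_1 = rect_poly(20, 58, 26, 62),  RF_2 = rect_poly(90, 30, 96, 34),
    SH_1 = rect_poly(112, 5, 122, 12), SH_2 = rect_poly(100, 50, 112, 60),
    TR_1 = rect_poly(40, 20, 43, 22),  TR_2 = rect_poly(118, 40, 121, 42)
  )
  farm_layout(paddock, pastures, resources, origin)
}

# --- local planar projection ------------------------------------------------

# Ellipsoidal radii of curvature (WGS84) at a latitude, used so that local
# east/north metres agree with geodesic distances to < 0.005% at farm scale.
.wgs84 <- c(a = 6378137, e2 = 0.00669437999014)

local_radii <- function(lat_deg) {
  phi <- lat_deg * pi / 180
  s2 <- .wgs84["e2"] * sin(phi)^2
  list(M = unname(.wgs84["a"] * (1 - .wgs84["e2"]) / (1 - s2)^1.5),
       N = unname(.wgs84["a"] / sqrt(1 - s2)),
       cosphi = cos(phi))
}

#' Project geodetic coordinates to the local planar frame
#'
#' Local equirectangular projection about `origin`: east
#' `x = N(phi0) cos(phi0) * dlon`, north `y = M(phi0) * dlat`, with `M`, `N`
#' the WGS84 meridional and prime-vertical radii of curvature at the origin
#' latitude. Intended for farm-scale points only (within 0.05 degrees of the
#' origin), where the planar distance matches the geodesic to well under
#' 0.05%.
#'
#' @param lat,lon Numeric vectors, degrees.
#' @param origin `c(lat, lon)` degrees.
#' @return A data.frame with columns `x`, `y` (m).
#' @seealso [unproject_from_local()] for the exact inverse.
#' @export
project_to_local <- function(lat, lon, origin) {
  dlat <- lat - origin[1]
  dlon <- lon - origin[2]
  if (any(abs(dlat) >= 0.05 | abs(dlon) >= 0.05, na.rm = TRUE))
    stop("point outside the farm-scale projection range (0.05 deg of origin)")
  r <- local_radii(origin[1])
  data.frame(x = r$N * r$cosphi * dlon * pi / 180,
             y = r$M * dlat * pi / 180)
}

#' Inverse of [project_to_local()]
#'
#' @param x,y Numeric vectors, local metres.
#' @param origin `c(lat, lon)` degrees.
#' @return A data.frame with columns `lat`, `lon` (deg).
#' @export
unproject_from_local <- function(x, y, origin) {
  r <- local_radii(origin[1])
  data.frame(lat = origin[1] + (y / r$M) * 180 / pi,
             lon = origin[2] + (x / (r$N * r$cosphi)) * 180 / pi)
}

# --- grid -------------------------------------------------------------------

#' Define the analysis grid
#'
#' @param origin_x,origin_y South-west corner of the grid (m, local frame).
#' @param cell_size Cell edge length in metres (default 3, giving the
#'   3 x 3 m squares of the analysis).
#' @param n_rows,n_cols Grid dimensions.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size = 3, n_rows, n_cols) {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' Grid covering a farm layout
#'
#' Anchors the grid at the south-west corner of the layout's planar extent
#' with east/north axes, sized to cover the paddock and all pastures.
#'
#' @param layout A [farm_layout()].
#' @param cell_size Cell edge (m), default 3.
#' @return A [grid_spec()].
#' @export
grid_for_layout <- function(layout, cell_size = 3) {
  ex <- layout$extent
  grid_spec(origin_x = ex["min_x"], origin_y = ex["min_y"],
            cell_size = cell_size,
            n_rows = ceiling((ex["max_y"] - ex["min_y"]) / cell_size),
            n_cols = ceiling((ex["max_x"] - ex["min_x"]) / cell_size))
}

#' Assign planar points to grid squares
#'
#' Cells are half-open intervals `[k*s, (k+1)*s)` in each axis, so a point
#' exactly on a shared edge belongs to the higher-index cell and every
#' in-grid point gets exactly one square.
#'
#' @param x,y Numeric vectors, local metres.
#' @param grid A [grid_spec()].
#' @return A data.frame with integer columns `row`, `col` (0-based).
#' @export
square_of <- function(x, y, grid) {
  row <- floor((y - grid$origin_y) / grid$cell_size)
  col <- floor((x - grid$origin_x) / grid$cell_size)
  bad <- row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols
  if (any(bad, na.rm = TRUE))
    stop(sum(bad, na.rm = TRUE), " point(s) outside the grid extent")
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Linear key for a grid square
#'
#' `row * n_cols + col`; convenient for tabulating distinct squares.
#' @param row,col 0-based square indices.
#' @param grid A [grid_spec()].
#' @return Integer (double) vector of unique keys.
#' @export
square_key <- function(row, col, grid) row * grid$n_cols + col

# point-in-polygon; thin wrapper so the engine is swappable in one place
point_in_poly <- function(x, y, poly) {
  mgcv::in.out(rbind(poly, poly[1, ]), cbind(x, y))
}

#' Label grid squares by the resource at their centre
#'
#' Each square takes the label of the resource zone containing its centre;
#' squares whose centre lies in no resource zone are `PADDOCK` or `PASTURE`
#' by containing polygon. Squares whose centre is in neither are `NA` (and
#' an error when `strict = TRUE`).
#'
#' @param row,col 0-based square indices (vectors).
#' @param layout A [farm_layout()].
#' @param grid A [grid_spec()].
#' @param strict Error on squares outside paddock and pasture?
#' @return Character vector of labels from [location_labels()].
#' @export
location_of <- function(row, col, layout, grid, strict = FALSE) {
  cx <- grid$origin_x + (col + 0.5) * grid$cell_size
  cy <- grid$origin_y + (row + 0.5) * grid$cell_size
  lab <- rep(NA_character_, length(cx))
  for (nm in names(layout$resources)) {
    hit <- is.na(lab) & point_in_poly(cx, cy, layout$resources[[nm]])
    lab[hit] <- nm
  }
  todo <- is.na(lab)
  if (any(todo)) {
    inpad <- point_in_poly(cx[todo], cy[todo], layout$paddock)
    lab[todo][inpad] <- "PADDOCK"
  }
  todo <- is.na(lab)
  if (any(todo)) {
    inpast <- rep(FALSE, sum(todo))
    for (p in layout$pastures)
      inpast <- inpast | point_in_poly(cx[todo], cy[todo], p$poly)
    lab[todo][inpast] <- "PASTURE"
  }
  if (strict && anyNA(lab))
    stop(sum(is.na(lab)), " square centre(s) in neither paddock nor pasture")
  lab
}

# --- layout serialization ---------------------------------------------------

#' Write a farm layout to a GeoJSON-flavoured file
#'
#' Polygons are stored as GeoJSON `Polygon` features whose coordinates are
#' local planar metres (not lon/lat); each feature carries a `label`
#' property, pastures additionally an `open_days` list and a `gate` point.
#' The geodetic origin lives in the top-level `properties`.
#'
#' @param layout A [farm_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_farm_layout <- function(layout, path) {
  feat <- function(label, role, poly, extra = list()) {
    c(list(type = "Feature",
           properties = c(list(label = label, role = role), extra),
           geometry = list(type = "Polygon",
                           coordinates = list(unname(lapply(
                             seq_len(nrow(poly)),
                             function(i) unname(poly[i, ])))))))
  }
  feats <- list(feat("PADDOCK", "paddock", layout$paddock))
  for (nm in names(layout$pastures)) {
    p <- layout$pastures[[nm]]
    feats <- c(feats, list(feat("PASTURE", "pasture", p$poly,
                                list(name = nm, open_days = p$open_days,
                                     gate = p$gate))))
  }
  for (nm in names(layout$resources))
    feats <- c(feats, list(feat(nm, "resource", layout$resources[[nm]])))
  doc <- list(type = "FeatureCollection",
              properties = list(origin = unname(layout$origin),
                                crs = "local-planar-m"),
              features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a farm layout written by [write_farm_layout()]
#'
#' @param path File path.
#' @return A [farm_layout()].
#' @export
read_farm_layout <- function(path) {
  doc <- jsonlite::read_json(path)
  poly_of <- function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    colnames(m) <- c("x", "y")
    m
  }
  paddock <- NULL; pastures <- list(); resources <- list()
  for (f in doc$features) {
    role <- f$properties$role
    if (role == "paddock") paddock <- poly_of(f)
    else if (role == "pasture")
      pastures[[f$properties$name]] <-
        list(poly = poly_of(f),
             open_days = as.integer(unlist(f$properties$open_days)),
             gate = as.numeric(unlist(f$properties$gate)))
    else resources[[f$properties$label]] <- poly_of(f)
  }
  origin <- as.numeric(unlist(doc$properties$origin))
  farm_layout(paddock, pastures, resources, origin)
}
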