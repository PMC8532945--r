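# Seasonal occupancy heatmaps of the gridded farm with resource outlines.

#' Season windows over the observation period
#'
#' Day-index windows: days `1..summer_days` are summer, the rest winter
#' (defaults 159 + 68 = 227). The two windows partition the study.
#'
#' @param summer_days,winter_days Day counts.
#' @return Named list of integer day vectors.
#' @export
season_windows <- function(summer_days = 159, winter_days = 68) {
  list(summer = seq_len(summer_days),
       winter = seq(summer_days + 1, summer_days + winter_days))
}

#' Per-square mean frequency over a season
#'
#' Averages each square's daily usage frequency over the season's days,
#' counting days on which the square was unvisited as zero; squares never
#' visited stay zero. The result has the grid's dimensions.
#'
#' @param frequencies Tibble from [square_frequencies()].
#' @param season `"summer"` or `"winter"`, or an integer day vector.
#' @param grid A [grid_spec()].
#' @param windows From [season_windows()].
#' @param n_days Number of season days to average over; defaults to the
#'   days present in `frequencies` within the window.
#' @return Numeric `n_rows x n_cols` matrix of mean frequency (percent).
#' @export
seasonal_heat_grid <- function(frequencies, season, grid,
                               windows = season_windows(), n_days = NULL) {
  days <- if (is.character(season)) windows[[season]] else season
  f <- frequencies[frequencies$day %in% days, ]
  if (nrow(f) == 0) stop("no frequency rows fall in the requested season")
  if (is.null(n_days)) n_days <- length(unique(f$day))
  m <- matrix(0, grid$n_rows, grid$n_cols)
  sums <- tapply(f$frequency, list(factor(f$row, levels = 0:(grid$n_rows - 1)),
                                   factor(f$col, levels = 0:(grid$n_cols - 1))),
                 sum, default = 0)
  m[] <- sums / n_days
  m
}

resource_outline_colors <- function() {
  c(FS = "#7CCD7C", CF = "#EE9A00", LH = "black", RF = "gold",
    SH = "darkblue", TR = "steelblue")
}

#' Render an occupancy heatmap
#'
#' Raster of the heat grid with a colour scale capped (and saturated) at
#' `cap` percent so that extreme resource squares do not flatten the
#' paddock's dynamic range, plus resource polygon outlines in the
#' conventional colours (straw racks yellow, lying halls black, feed
#' stalls green). An all-zero grid renders as a uniform background with a
#' note, not an error. When `file` is given the plot is written there and
#' the underlying matrix to `<file>.csv` alongside, so rendering never
#' alters the data.
#'
#' @param heat_grid Matrix from [seasonal_heat_grid()].
#' @param layout A [farm_layout()].
#' @param grid A [grid_spec()].
#' @param cap Colour-scale maximum, percent (default 0.3).
#' @param file Optional output path (`.png` or `.svg` by extension).
#' @param title Plot title.
#' @return The ggplot object, invisibly.
#' @export
render_heatmap <- function(heat_grid, layout, grid, cap = 0.3, file = NULL,
                           title = "Square usage frequency (%)") {
  df <- data.frame(
    x = grid$origin_x + (rep(0:(grid$n_cols - 1), each = grid$n_rows) + 0.5) *
      grid$cell_size,
    y = grid$origin_y + (rep(0:(grid$n_rows - 1), times = grid$n_cols) + 0.5) *
      grid$cell_size,
    z = pmin(as.vector(heat_grid), cap))
  polys <- lapply(names(layout$resources), function(nm) {
    p <- layout$resources[[nm]]
    data.frame(label = nm, grp = substr(nm, 1, 2), x = p[, 1], y = p[, 2])
  })
  polys <- do.call(rbind, polys)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = z)) +
    ggplot2::scale_fill_gradientn(
      colours = c("white", "yellow", "orange", "red", "darkred"),
      limits = c(0, cap), name = "%") +
    ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(group = label, colour = grp),
      fill = NA, linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = resource_outline_colors(),
                                 name = "resource") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "east (m)", y = "north (m)") +
    ggplot2::theme_minimal()
  if (all(heat_grid == 0))
    gg <- gg + ggplot2::labs(subtitle = "no occupancy recorded")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "svg") {
      grDevices::svg(file, width = 9, height = 6)
    } else {
      grDevices::png(file, width = 1350, height = 900, res = 150,
                     type = "cairo")
    }
    print(gg)
    grDevices::dev.off()
    utils::write.csv(heat_grid, paste0(file, ".csv"), row.names = FALSE)
  }
  invisible(gg)
}
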