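# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately naive (loops, ray casting) and share no code
# with the implementation paths they check.

tiny_layout <- function(n_days = 10, summer_days = 6) {
  paddock <- matrix(c(0, 0, 30, 0, 30, 24, 0, 24), ncol = 2, byrow = TRUE)
  pastures <- list(
    PASTURE_A = list(poly = matrix(c(30, 0, 60, 0, 60, 24, 30, 24),
                                   ncol = 2, byrow = TRUE),
                     open_days = seq_len(summer_days),
                     gate = c(30, 12)))
  resources <- list(
    FS_1 = matrix(c(1, 1, 7, 1, 7, 5, 1, 5), ncol = 2, byrow = TRUE),
    LH_1 = matrix(c(12, 14, 22, 14, 22, 22, 12, 22), ncol = 2, byrow = TRUE),
    LH_2 = matrix(c(1, 14, 9, 14, 9, 22, 1, 22), ncol = 2, byrow = TRUE),
    RF_1 = matrix(c(24, 2, 28, 2, 28, 5, 24, 5), ncol = 2, byrow = TRUE),
    SH_1 = matrix(c(24, 8, 28, 8, 28, 12, 24, 12), ncol = 2, byrow = TRUE),
    TR_1 = matrix(c(13, 1, 18, 1, 18, 5, 13, 5), ncol = 2, byrow = TRUE))
  farm_layout(paddock, pastures, resources, origin = c(54.3, 9.1))
}

tiny_cfg <- function(...) {
  sim_config(n_horses = 3, n_days = 10, summer_days = 6, rng_seed = 42, ...)
}

tiny_metas <- function(n = 3, n_days = 10) {
  horse_metas(n, n_newcomers = 0, n_days = n_days, seed = 5)
}

# independent even-odd ray-casting point-in-polygon oracle
ray_cast <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(i) {
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      xi <- poly[k, 1]; yi <- poly[k, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > py[i]) != (yj > py[i]) &&
          px[i] < (xj - xi) * (py[i] - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- k
    }
    inside
  }, logical(1))
}

# brute-force half-open cell containment over every cell of the grid
brute_square_of <- function(x, y, grid) {
  out <- matrix(NA_integer_, length(x), 2)
  for (r in 0:(grid$n_rows - 1)) for (cc in 0:(grid$n_cols - 1)) {
    y0 <- grid$origin_y + r * grid$cell_size
    x0 <- grid$origin_x + cc * grid$cell_size
    hit <- y >= y0 & y < y0 + grid$cell_size &
      x >= x0 & x < x0 + grid$cell_size
    out[hit, 1] <- r
    out[hit, 2] <- cc
  }
  out
}

# a clean one-day fixture placing a horse in chosen squares at chosen times
fixes_at_squares <- function(layout, grid, hour, key_rowcol, horse_id = 1L,
                             fix_interval = 10, day = 1) {
  # key_rowcol: list per fix index within the hour of c(row, col)
  n <- length(key_rowcol)
  cs <- grid$cell_size
  x <- vapply(key_rowcol, function(rc) grid$origin_x + (rc[2] + 0.5) * cs, 0)
  y <- vapply(key_rowcol, function(rc) grid$origin_y + (rc[1] + 0.5) * cs, 0)
  ll <- unproject_from_local(x, y, layout$origin)
  t_local <- as.numeric(as.POSIXct("2020-06-01", tz = "UTC")) +
    (day - 1) * 86400 + hour * 3600 + (seq_len(n) - 1) * fix_interval
  tibble::tibble(horse_id = horse_id,
                 timestamp_utc = as.POSIXct(t_local - 7200,
                                            origin = "1970-01-01", tz = "UTC"),
                 timestamp_local = as.POSIXct(t_local, origin = "1970-01-01",
                                              tz = "UTC"),
                 lat = ll$lat, lon = ll$lon, height = 20,
                 speed = 0, step_distance = 0)
}

# full synthetic day of fixes cycling through k squares each hour
constructed_day <- function(layout, grid, k, horse_id = 1L) {
  rcs <- lapply(0:(k - 1), function(i) c(i %/% 5, i %% 5))
  parts <- lapply(0:23, function(h)
    fixes_at_squares(layout, grid, h,
                     rep(rcs, length.out = 360), horse_id = horse_id))
  do.call(rbind, parts)
}

# balanced design: 2 breeds x 2 sexes x 2 animals each, ages orthogonal to
# the factors, every animal observed on every day
balanced_usage <- function(n_days = 3, sd = 1, seed = 13,
                           day_effect = c(0, 4, -2)) {
  metas <- tibble::tibble(
    horse_id = 1:8,
    breed = factor(rep(c("warmblood", "pony"), each = 4),
                   levels = c("warmblood", "pony")),
    sex = factor(rep(c("gelding", "gelding", "mare", "mare"), 2),
                 levels = c("gelding", "mare")),
    age = rep(c(10, 20), 4),
    entry_day = 1L)
  grid <- expand.grid(horse_id = 1:8, day = seq_len(n_days))
  d <- merge(grid, metas, by = "horse_id")
  set.seed(seed)
  d$squares_per_hour <- 40 + 3 * (d$breed == "pony") - 2 * (d$sex == "mare") +
    day_effect[d$day] + stats::rnorm(nrow(d), 0, sd)
  usage <- tibble::tibble(horse_id = d$horse_id, date = as.character(d$day),
                          n_fixes = 8640L, hours_covered = 24L,
                          squares_per_hour = d$squares_per_hour,
                          included = TRUE, day = d$day,
                          variant = "with_pasture")
  list(usage = usage, metas = metas)
}
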