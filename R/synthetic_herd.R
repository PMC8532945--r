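# Behavioural-state herd simulator: generates GPS logger datasets with the
# statistical structure of a 52-horse active-stable study (summer pasture
# windows, newcomer entries, GPS noise, spike outliers) plus the ground
# truth needed for parameter-recovery tests.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed for:
#' 227 observation days (159 summer + 68 winter), one fix per 10 s, twice
#' daily ~90 min pasture access in summer, an age effect of -0.6 distinct
#' squares per hour per year of age acting on movement, and a per-animal
#' random effect on mobility.
#'
#' @param n_horses Herd size (default 52).
#' @param n_days Observation days (default 227).
#' @param summer_days Days 1..summer_days are summer (default 159); the
#'   remaining `n_days - summer_days` are winter.
#' @param fix_interval GPS sampling interval in seconds (default 10).
#' @param age_slope Change in mobility score per year of age
#'   (default -0.6 squares/h per year).
#' @param age_ref Age (years) at which the slope term vanishes.
#' @param animal_sd SD of the per-horse random mobility effect, on the
#'   squares/h scale (default 8).
#' @param mobility_base Baseline mobility score (squares/h scale) of an
#'   average-aged horse (default 50).
#' @param mobility_gamma Exponent calibrating how the mobility score maps to
#'   the behavioural switch rate (default 1.8). Chosen so that one unit of
#'   mobility score produces about one distinct square per hour in the
#'   response, i.e. the score really is on the squares/h scale; the raw
#'   switch rate alone under-transmits because travel time and dwell
#'   spread also shape the count.
#' @param gps_noise_sd Isotropic GPS noise SD in metres (default 1.5).
#' @param spike_prob Probability that a fix is replaced by a far teleport
#'   (>160 m), exercising the outlier filters (default 0).
#' @param dropout_prob Probability that a fix is missing (default 0.02).
#' @param pasture_windows List of `c(start, end)` second-of-day pairs during
#'   which open pasture is accessible in summer (default 07:00-08:30 and
#'   18:00-19:30).
#' @param graze_prob Probability a horse is on pasture during an open window.
#' @param travel_speed Walking speed between targets, m/s.
#' @param wander_sd SD (m) of position jitter while dwelling at a resource.
#' @param graze_step SD (m) of the per-fix grazing drift on pasture.
#' @param dwell_mean Named mean dwell durations (s) per behavioural state.
#' @param state_weights Sampling weights of the non-grazing states.
#' @param utc_offset Seconds local time is ahead of UTC (default 7200).
#' @param rng_seed Root seed; per-horse-day substreams are derived from it
#'   by counter so horse subsets reproduce.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_horses = 52, n_days = 227, summer_days = 159,
                       fix_interval = 10,
                       age_slope = -0.6, age_ref = 15.5, animal_sd = 8,
                       mobility_base = 50, mobility_gamma = 1.8,
                       gps_noise_sd = 1.5, spike_prob = 0,
                       dropout_prob = 0.02,
                       pasture_windows = list(c(7 * 3600, 7 * 3600 + 5400),
                                              c(18 * 3600, 18 * 3600 + 5400)),
                       graze_prob = 0.9,
                       travel_speed = 1.1, wander_sd = 1.0, graze_step = 0.8,
                       dwell_mean = c(rest = 2400, feed = 1200, stand = 900,
                                      drink = 120, wander = 600, graze = 1500),
                       state_weights = c(rest = 0.25, feed = 0.25,
                                         stand = 0.2, drink = 0.1,
                                         wander = 0.2),
                       utc_offset = 7200, rng_seed = 1L) {
  stopifnot(summer_days <= n_days, fix_interval > 0,
            spike_prob >= 0, spike_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate horse metadata for a simulated herd
#'
#' Breed classes default to a 31/6/15 warmblood/pony/other split (scaled
#' proportionally for other herd sizes); sexes are geldings and mares only;
#' ages are uniform on 2..29 years; `n_newcomers` horses enter the herd
#' after day 1 at random entry days.
#'
#' @param n_horses Herd size.
#' @param n_newcomers Horses with `entry_day > 1` (default 12 at the default
#'   herd size, scaled otherwise).
#' @param n_days Observation days (entry days are drawn in `2..n_days/2`).
#' @param breed_split Named integer target counts; scaled to `n_horses`.
#' @param seed RNG seed for ages/sexes/entry days.
#' @return A tibble with columns `horse_id`, `breed`, `sex`, `age`,
#'   `entry_day`.
#' @export
horse_metas <- function(n_horses = 52,
                        n_newcomers = round(12 * n_horses / 52),
                        n_days = 227,
                        breed_split = c(warmblood = 31, pony = 6, other = 15),
                        seed = 1L) {
  counts <- round(breed_split / sum(breed_split) * n_horses)
  counts[1] <- n_horses - sum(counts[-1])
  with_seed(seed, {
    breed <- factor(rep(names(counts), counts), levels = names(breed_split))
    sex <- factor(sample(c("gelding", "mare"), n_horses, replace = TRUE),
                  levels = c("gelding", "mare"))
    age <- sample(2:29, n_horses, replace = TRUE)
    entry <- rep(1L, n_horses)
    if (n_newcomers > 0) {
      idx <- sample(n_horses, n_newcomers)
      entry[idx] <- sample(2:max(2, n_days %/% 2), n_newcomers, replace = TRUE)
    }
    tibble::tibble(horse_id = seq_len(n_horses), breed = breed, sex = sex,
                   age = as.numeric(age), entry_day = entry)
  })
}

# run expr under a temporary RNG seed, restoring caller state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic substream seed per (root, horse, day), < 2^31
day_seed <- function(root, horse_id, day) {
  as.integer((as.numeric(root) + horse_id * 131071 + day * 524287 + 11) %%
               2147483629)
}

clamp_rect <- function(xy, rect, inset = 0.25) {
  xy[, 1] <- pmin(pmax(xy[, 1], rect[1] + inset), rect[2] - inset)
  xy[, 2] <- pmin(pmax(xy[, 2], rect[3] + inset), rect[4] - inset)
  xy
}

poly_rect <- function(poly)  # (xmin, xmax, ymin, ymax)
  c(range(poly[, 1]), range(poly[, 2]))

# local-day start (seconds since epoch, interpreted as local clock) for an
# observation-day index; day 1 = 2020-06-01
.study_epoch <- as.numeric(as.POSIXct("2020-06-01", tz = "UTC"))

day_start_local <- function(day) .study_epoch + (day - 1) * 86400

#' Simulate one horse-day of GPS fixes
#'
#' A semi-Markov behavioural state machine: the horse alternates between
#' dwelling at a target (rest in a lying hall, feed at a feed stall, drink
#' at a trough, stand at a straw rack or shelter, graze on open pasture
#' during summer windows, or loiter at a random paddock spot) and walking
#' to the next target along a straight path with lateral jitter, routed
#' through the pasture gate when crossing the paddock boundary. Dwell
#' durations are exponential with state-specific means divided by the
#' horse's mobility factor, so mobility is monotone in
#' `mobility_base + age_slope * (age - age_ref) + animal_effect`.
#' True positions are perturbed by isotropic Gaussian GPS noise; with
#' probability `spike_prob` a fix teleports 160-500 m away; fixes drop out
#' independently with probability `dropout_prob`.
#'
#' @param horse One-row data.frame as from [horse_metas()].
#' @param day Observation-day index (>= `horse$entry_day`).
#' @param layout A [farm_layout()]; the simulator assumes rectangular
#'   paddock/pasture/resource polygons.
#' @param cfg A [sim_config()].
#' @param animal_effect Per-horse random mobility effect (squares/h scale).
#' @return A tibble of fixes (`horse_id`, `timestamp_utc`,
#'   `timestamp_local`, `lat`, `lon`, `height`, `speed`, `step_distance`)
#'   with attributes `spikes` (integer slot indices into the returned rows)
#'   and `n_slots`.
#' @export
simulate_day <- function(horse, day, layout, cfg, animal_effect = 0) {
  if (day < horse$entry_day)
    stop("horse ", horse$horse_id, " has no data before entry day ",
         horse$entry_day)
  with_seed(day_seed(cfg$rng_seed, horse$horse_id, day), {
    dt <- cfg$fix_interval
    n_slots <- as.integer(86400 / dt)
    is_summer <- day <= cfg$summer_days
    open <- Filter(function(p) day %in% p$open_days, layout$pastures)
    windows <- if (is_summer && length(open)) cfg$pasture_windows else list()

    mob <- cfg$mobility_base + cfg$age_slope * (horse$age - cfg$age_ref) +
      animal_effect
    mob_factor <- (max(mob, 5) / cfg$mobility_base)^cfg$mobility_gamma

    pad_rect <- poly_rect(layout$paddock)
    res_rects <- lapply(layout$resources, poly_rect)
    # dwell targets by state
    zones <- list(
      rest  = res_rects[grep("^LH_", names(res_rects))],
      feed  = res_rects[grep("^(FS|CF)_", names(res_rects))],
      drink = res_rects[grep("^TR_", names(res_rects))],
      stand = res_rects[grep("^(RF|SH)_", names(res_rects))]
    )
    pos <- matrix(NA_real_, n_slots, 2)
    cur <- c(mean(pad_rect[1:2]), mean(pad_rect[3:4]))
    cur_area <- pad_rect       # rectangle the horse is currently confined to
    cur_gate <- NULL           # gate of the pasture it is in, if any
    i <- 1L
    while (i <= n_slots) {
      t_now <- (i - 1L) * dt
      win <- NULL
      for (w in windows) if (t_now >= w[1] && t_now < w[2]) win <- w
      if (!is.null(win) && stats::runif(1) < cfg$graze_prob) {
        state <- "graze"
        pz <- open[[sample.int(length(open), 1)]]
        rect <- poly_rect(pz$poly)
        target_area <- rect; target_gate <- pz$gate
      } else {
        state <- sample(names(cfg$state_weights), 1,
                        prob = cfg$state_weights)
        rect <- if (state == "wander") pad_rect
        else {
          zl <- zones[[state]]
          zl[[sample.int(length(zl), 1)]]
        }
        target_area <- pad_rect; target_gate <- NULL
      }
      anchor <- c(stats::runif(1, rect[1], rect[2]),
                  stats::runif(1, rect[3], rect[4]))

      # travel legs; cross the gate when changing between paddock and pasture
      crossing <- !identical(cur_area, target_area)
      gate <- if (crossing) (if (is.null(cur_gate)) target_gate else cur_gate)
      legs <- if (crossing) list(list(gate, cur_area), list(anchor, target_area))
              else list(list(anchor, cur_area))
      for (leg in legs) {
        if (i > n_slots) break
        to <- leg[[1]]; leg_rect <- leg[[2]]
        L <- sqrt(sum((to - cur)^2))
        nst <- max(1L, ceiling(L / (cfg$travel_speed * dt)))
        take <- min(nst, n_slots - i + 1L)
        fr <- seq_len(take) / nst
        pts <- cbind(cur[1] + fr * (to[1] - cur[1]),
                     cur[2] + fr * (to[2] - cur[2]))
        if (take > 1)
          pts[-take, ] <- pts[-take, , drop = FALSE] +
            stats::rnorm(2 * (take - 1), 0, 0.5)
        pts <- clamp_rect(pts, leg_rect)
        pos[i:(i + take - 1L), ] <- pts
        i <- i + take
        cur <- pts[take, ]
      }
      cur_area <- target_area; cur_gate <- target_gate
      if (i > n_slots) break

      # dwell
      dur <- stats::rexp(1) * cfg$dwell_mean[[state]] / mob_factor
      if (state == "graze") dur <- min(dur, max(win[2] - (i - 1L) * dt, dt))
      nd <- max(1L, min(round(dur / dt), n_slots - i + 1L))
      if (state == "graze") {
        steps <- matrix(stats::rnorm(2 * nd, 0, cfg$graze_step), ncol = 2)
        pts <- cbind(cur[1] + cumsum(steps[, 1]),
                     cur[2] + cumsum(steps[, 2]))
      } else {
        pts <- cbind(anchor[1] + stats::rnorm(nd, 0, cfg$wander_sd),
                     anchor[2] + stats::rnorm(nd, 0, cfg$wander_sd))
      }
      pts <- clamp_rect(pts, rect)
      pos[i:(i + nd - 1L), ] <- pts
      i <- i + nd
      cur <- pts[nd, ]
    }

    # observation process: noise, spikes, dropout
    noisy <- pos + stats::rnorm(2 * n_slots, 0, cfg$gps_noise_sd)
    spike_slot <- which(stats::runif(n_slots) < cfg$spike_prob)
    if (length(spike_slot)) {
      r <- stats::runif(length(spike_slot), 160, 500)
      th <- stats::runif(length(spike_slot), 0, 2 * pi)
      noisy[spike_slot, 1] <- pos[spike_slot, 1] + r * cos(th)
      noisy[spike_slot, 2] <- pos[spike_slot, 2] + r * sin(th)
    }
    keep <- stats::runif(n_slots) >= cfg$dropout_prob
    idx <- which(keep)
    ll <- unproject_from_local(noisy[idx, 1], noisy[idx, 2], layout$origin)
    t_local <- day_start_local(day) + (idx - 1L) * dt
    d <- c(0, sqrt(diff(noisy[idx, 1])^2 + diff(noisy[idx, 2])^2))
    dtsec <- c(dt, diff(idx) * dt)
    out <- tibble::tibble(
      horse_id = rep(horse$horse_id, length(idx)),
      timestamp_utc = as.POSIXct(t_local - cfg$utc_offset,
                                 origin = "1970-01-01", tz = "UTC"),
      timestamp_local = as.POSIXct(t_local, origin = "1970-01-01", tz = "UTC"),
      lat = ll$lat, lon = ll$lon,
      height = 20 + stats::rnorm(length(idx), 0, 2),
      speed = round(d / dtsec * 3.6, 3),
      step_distance = round(d, 3))
    attr(out, "spikes") <- match(spike_slot[spike_slot %in% idx], idx)
    attr(out, "n_slots") <- n_slots
    out
  })
}

# per-horse animal effect from a horse-keyed substream, so that simulating
# any subset of horses reproduces the full-study draws
animal_effects_for <- function(metas, cfg) {
  vapply(metas$horse_id, function(id)
    with_seed(day_seed(cfg$rng_seed, id, 0L),
              stats::rnorm(1, 0, cfg$animal_sd)), 0)
}

#' Simulate a full study
#'
#' Runs [simulate_day()] for every horse from its entry day to `n_days`,
#' returning the pooled fix table plus the ground truth needed for
#' recovery tests: per-horse animal effects, the configured age slope, and
#' the injected spike fixes.
#'
#' @param metas Tibble from [horse_metas()].
#' @param layout A [farm_layout()].
#' @param cfg A [sim_config()].
#' @param days Day indices to simulate (default `1:cfg$n_days`).
#' @return A list with `fixes` (tibble), `truth` (list with
#'   `animal_effects` tibble, `age_slope`, `spikes` tibble keyed by
#'   `horse_id` + `timestamp_utc`).
#' @export
simulate_study <- function(metas, layout, cfg, days = seq_len(cfg$n_days)) {
  stopifnot(nrow(metas) > 0)
  ae <- animal_effects_for(metas, cfg)
  parts <- list(); spikes <- list(); pi <- 1L
  for (h in seq_len(nrow(metas))) {
    horse <- metas[h, ]
    for (d in days[days >= horse$entry_day]) {
      fx <- simulate_day(horse, d, layout, cfg, animal_effect = ae[h])
      sp <- attr(fx, "spikes")
      if (length(sp))
        spikes[[pi]] <- tibble::tibble(horse_id = horse$horse_id, day = d,
                                       timestamp_utc = fx$timestamp_utc[sp])
      parts[[pi]] <- fx
      pi <- pi + 1L
    }
  }
  fixes <- bind_fix_tables(parts)
  truth <- list(
    animal_effects = tibble::tibble(horse_id = metas$horse_id,
                                    animal_effect = ae),
    age_slope = cfg$age_slope,
    spikes = if (length(spikes)) do.call(rbind, spikes)
             else tibble::tibble(horse_id = integer(), day = integer(),
                                 timestamp_utc = as.POSIXct(character(),
                                                            tz = "UTC")))
  list(fixes = fixes, truth = truth)
}

# fast column-wise concatenation of fix tibbles
bind_fix_tables <- function(parts) {
  parts <- parts[vapply(parts, nrow, 0L) > 0]
  if (!length(parts))
    return(tibble::tibble(horse_id = integer(),
                          timestamp_utc = as.POSIXct(character(), tz = "UTC"),
                          timestamp_local = as.POSIXct(character(), tz = "UTC"),
                          lat = double(), lon = double(), height = double(),
                          speed = double(), step_distance = double()))
  num <- function(col) unlist(lapply(parts, function(p) as.numeric(p[[col]])),
                              use.names = FALSE)
  tibble::tibble(
    horse_id = unlist(lapply(parts, `[[`, "horse_id"), use.names = FALSE),
    timestamp_utc = as.POSIXct(num("timestamp_utc"),
                               origin = "1970-01-01", tz = "UTC"),
    timestamp_local = as.POSIXct(num("timestamp_local"),
                                 origin = "1970-01-01", tz = "UTC"),
    lat = num("lat"), lon = num("lon"), height = num("height"),
    speed = num("speed"), step_distance = num("step_distance"))
}

#' Simulate straight to the horse-day usage table
#'
#' Memory-lean path for recovery experiments: each horse-day is simulated,
#' gridded and reduced to its squares-per-hour summary immediately, so the
#' raw 8640-fix streams are never pooled. Filtering is skipped (intended
#' for clean configurations with `spike_prob = 0`).
#'
#' @inheritParams simulate_study
#' @param grid A [grid_spec()]; default [grid_for_layout()].
#' @param variant `"with_pasture"` or `"paddock_only"`.
#' @return A list with `usage` (tibble as from [horse_day_usage()]) and
#'   `truth` (animal effects + age slope).
#' @export
simulate_study_usage <- function(metas, layout, cfg,
                                 days = seq_len(cfg$n_days),
                                 grid = grid_for_layout(layout),
                                 variant = "with_pasture") {
  ae <- animal_effects_for(metas, cfg)
  rows <- list(); ri <- 1L
  for (h in seq_len(nrow(metas))) {
    horse <- metas[h, ]
    for (d in days[days >= horse$entry_day]) {
      fx <- simulate_day(horse, d, layout, cfg, animal_effect = ae[h])
      if (variant == "paddock_only") {
        xy <- project_to_local(fx$lat, fx$lon, layout$origin)
        fx <- fx[point_in_poly(xy$x, xy$y, layout$paddock), ]
      }
      u <- squares_per_hour(fx, grid, layout$origin,
                            fix_interval = cfg$fix_interval)
      u$day <- d
      u$variant <- variant
      rows[[ri]] <- u
      ri <- ri + 1L
    }
  }
  usage <- do.call(rbind, rows)
  list(usage = tibble::as_tibble(usage),
       truth = list(animal_effects = tibble::tibble(
                      horse_id = metas$horse_id, animal_effect = ae),
                    age_slope = cfg$age_slope))
}
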