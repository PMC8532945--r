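test_that("the day-inclusion boundary is inclusive at exactly 12 h of fixes", {
  expect_equal(min_fixes_per_day(10, 12), 4320L)
  expect_true(day_inclusion(4320))
  expect_false(day_inclusion(4319))
  expect_true(day_inclusion(8640))
})

test_that("squares per hour counts distinct cells per qualifying clock hour", {
  lay <- tiny_layout()
  g <- grid_for_layout(lay)

  # stationary horse: one square all day
  u <- squares_per_hour(constructed_day(lay, g, k = 1), g, lay$origin)
  expect_equal(u$squares_per_hour, 1)
  expect_equal(u$hours_covered, 24L)
  expect_true(u$included)

  # k distinct squares each hour by construction
  for (k in c(3, 7)) {
    u <- squares_per_hour(constructed_day(lay, g, k = k), g, lay$origin)
    expect_equal(u$squares_per_hour, k)
  }

  # sparse hours (below 90% coverage) are excluded from the mean
  sparse <- rbind(
    fixes_at_squares(lay, g, 0, replicate(360, c(0, 0), simplify = FALSE)),
    fixes_at_squares(lay, g, 1, replicate(100, c(2, 2), simplify = FALSE)))
  u <- squares_per_hour(sparse, g, lay$origin)
  expect_equal(u$hours_covered, 1L)
  expect_equal(u$squares_per_hour, 1)
  expect_false(u$included)  # 460 fixes < 4320

  # empty day
  u <- squares_per_hour(constructed_day(lay, g, 1)[0, ], g, lay$origin)
  expect_false(u$included)
  expect_true(is.na(u$squares_per_hour))
})

test_that("squares per hour equals a brute-force per-hour set cardinality", {
  lay <- tiny_layout()
  g <- grid_for_layout(lay)
  cfg <- tiny_cfg(dropout_prob = 0.05)
  m <- tiny_metas()
  fx <- simulate_day(m[1, ], 2, lay, cfg)
  u <- squares_per_hour(fx, g, lay$origin)

  xy <- project_to_local(fx$lat, fx$lon, lay$origin)
  sq <- square_of(xy$x, xy$y, g)
  hr <- floor((as.numeric(fx$timestamp_local) %% 86400) / 3600)
  counts <- integer(); dist <- integer()
  for (h in sort(unique(hr))) {
    sel <- hr == h
    counts <- c(counts, sum(sel))
    dist <- c(dist, nrow(unique(sq[sel, ])))
  }
  qual <- counts >= 324
  expect_equal(u$squares_per_hour, mean(dist[qual]))
  expect_equal(u$hours_covered, sum(qual))

  # invariance to fix-order shuffling within the day
  set.seed(2)
  fx_shuf <- fx[sample(nrow(fx)), ]
  expect_equal(squares_per_hour(fx_shuf, g, lay$origin)$squares_per_hour,
               u$squares_per_hour)
})

test_that("halving the fix rate never increases distinct squares per hour", {
  lay <- tiny_layout()
  g <- grid_for_layout(lay)
  cfg <- tiny_cfg(dropout_prob = 0)
  m <- tiny_metas()
  fx <- simulate_day(m[1, ], 3, lay, cfg)
  full <- squares_per_hour(fx, g, lay$origin)
  half <- squares_per_hour(fx[seq(1, nrow(fx), by = 2), ], g, lay$origin,
                           fix_interval = 20)
  expect_lte(half$squares_per_hour, full$squares_per_hour)
})

test_that("square frequencies are percentages that sum to 100 per day", {
  lay <- tiny_layout()
  g <- grid_for_layout(lay)

  # all fixes in one square
  fx <- fixes_at_squares(lay, g, 5, replicate(50, c(2, 3), simplify = FALSE))
  f <- square_frequencies(fx, g, lay)
  expect_equal(nrow(f), 1)
  expect_equal(f$frequency, 100)

  # even split over 4 squares -> 25% each
  rcs <- list(c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  fx <- fixes_at_squares(lay, g, 5, rep(rcs, 25))
  f <- square_frequencies(fx, g, lay)
  expect_equal(sort(f$frequency), rep(25, 4))

  # random multi-horse days match a brute-force tally and conserve mass
  cfg <- tiny_cfg(dropout_prob = 0.03)
  m <- tiny_metas(3)
  s <- simulate_study(m, lay, cfg, days = 1:2)
  f <- square_frequencies(s$fixes, g, lay)
  sums <- tapply(f$frequency, f$day, sum)
  expect_true(all(abs(sums - 100) < 1e-9 * 100))

  xy <- project_to_local(s$fixes$lat, s$fixes$lon, lay$origin)
  sq <- square_of(xy$x, xy$y, g)
  date <- format(s$fixes$timestamp_local, "%Y-%m-%d")
  d1 <- date == min(date)
  key <- paste(sq$row[d1], sq$col[d1])
  tab <- table(key)
  f1 <- f[f$day == 1, ]
  expect_equal(nrow(f1), length(tab))
  expect_equal(f1$n_fixes[order(paste(f1$row, f1$col))],
               as.integer(tab[sort(names(tab))]))
  expect_equal(attr(f, "n_visited_squares"),
               length(unique(paste(sq$row, sq$col))))
})

test_that("location usage averages square frequencies per label", {
  lay <- tiny_layout()
  g <- grid_for_layout(lay)
  # pick cells carrying the wanted labels by sweeping the whole grid
  all_rc <- expand.grid(row = 0:(g$n_rows - 1), col = 0:(g$n_cols - 1))
  lab <- location_of(all_rc$row, all_rc$col, lay, g)
  cell <- function(want, k = 1) as.integer(all_rc[which(lab == want)[k], ])
  rc_tr <- cell("TR_1"); rc_pad <- cell("PADDOCK")

  # single-square location holding 10% of fixes reports 10%
  fx <- fixes_at_squares(lay, g, 5, c(replicate(10, rc_tr, simplify = FALSE),
                                      replicate(90, rc_pad, simplify = FALSE)))
  f <- square_frequencies(fx, g, lay)
  lu <- location_usage(f)
  expect_equal(lu$mean_frequency[lu$location == "TR_1"], 10)
  expect_equal(lu$mean_frequency[lu$location == "PADDOCK"], 90)

  # a location of 2 squares holding 10% and 0%: mean-over-squares gives 5%
  rc_lh <- cell("LH_1", 1); rc_lh2 <- cell("LH_1", 2)
  fx <- fixes_at_squares(lay, g, 5, c(replicate(10, rc_lh, simplify = FALSE),
                                      replicate(90, rc_pad, simplify = FALSE)))
  f <- square_frequencies(fx, g, lay)
  f2 <- rbind(f, f[1, ])
  f2$frequency[nrow(f2)] <- 0
  f2$row[nrow(f2)] <- rc_lh2[1]; f2$col[nrow(f2)] <- rc_lh2[2]
  f2$location[nrow(f2)] <- "LH_1"
  lu <- location_usage(f2)
  expect_equal(lu$mean_frequency[lu$location == "LH_1"], 5)
  # absent locations are absent, not zero
  expect_false("SH_1" %in% lu$location)

  # group-mean oracle on a simulated day (filtered, so labels are complete)
  cfg <- tiny_cfg()
  s <- simulate_study(tiny_metas(2), lay, cfg, days = 1:1)
  fx <- filter_fixes(s$fixes, lay)$fixes
  f <- square_frequencies(fx, g, lay)
  lu <- location_usage(f)
  for (loc in lu$location)
    expect_equal(lu$mean_frequency[lu$location == loc],
                 mean(f$frequency[f$location %in% loc]))
})

test_that("paddock-only squares per hour never exceeds with-pasture", {
  lay <- tiny_layout()
  g <- grid_for_layout(lay)
  cfg <- tiny_cfg(dropout_prob = 0)
  m <- tiny_metas(2)
  s <- simulate_study(m, lay, cfg, days = 1:3)  # summer days with grazing
  with_p <- horse_day_usage(s$fixes, lay, g, variant = "with_pasture")
  pad <- clip_to_areas(s$fixes, lay, include_pasture = FALSE)$fixes
  pad_only <- horse_day_usage(pad, lay, g, variant = "paddock_only")
  j <- merge(with_p, pad_only, by = c("horse_id", "date"))
  j <- j[j$included.x & j$included.y, ]
  expect_gt(nrow(j), 0)
  expect_true(all(j$squares_per_hour.y <= j$squares_per_hour.x))
})
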