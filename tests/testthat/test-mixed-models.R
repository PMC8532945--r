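test_that("fixed effects match an independent GLS computation at the REML variances", {
  b <- balanced_usage(n_days = 3)
  f <- fit_model1(b$usage, b$metas)
  fit <- f$fit
  X <- lme4::getME(fit, "X")
  Z <- as.matrix(lme4::getME(fit, "Z"))
  V <- f$sigma_a2 * Z %*% t(Z) + f$sigma_e2 * diag(nrow(X))
  y <- f$data$squares_per_hour
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(unname(lme4::fixef(fit)), as.vector(beta), tolerance = 1e-6)
})

test_that("balanced no-random-effect LSMs equal cell means", {
  b <- balanced_usage(n_days = 3, sd = 0.5)
  f <- fit_model1(b$usage, b$metas)
  merged <- merge(b$usage, b$metas, by = "horse_id")
  for (fac in c("breed", "sex")) {
    lsm <- if (fac == "breed") f$lsm_breed$lsm else f$lsm_sex$lsm
    cells <- tapply(merged$squares_per_hour, merged[[fac]], mean)
    expect_equal(lsm$lsm, as.vector(cells[lsm$level]), tolerance = 1e-8)
  }
})

test_that("null simulated data recover zero animal variance and zero slope", {
  lay <- tiny_layout(n_days = 12, summer_days = 8)
  g <- grid_for_layout(lay)
  m <- horse_metas(16, n_newcomers = 0, n_days = 12, seed = 4)
  cfg <- sim_config(n_horses = 16, n_days = 12, summer_days = 8,
                    animal_sd = 0, age_slope = 0, rng_seed = 77)
  r <- simulate_study_usage(m, lay, cfg, days = 1:10, grid = g)
  f <- fit_model1(r$usage, m)
  # variance of the (absent) animal effect is near zero relative to residual
  expect_lt(f$sigma_a2, 0.25 * f$sigma_e2)
  # 95% CI of the age slope covers the true value 0
  ci <- f$age_slope["estimate"] + c(-1, 1) * 1.96 * f$age_slope["se"]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("rank-deficient designs are refused with the aliased term named", {
  b <- balanced_usage()
  metas1 <- b$metas
  metas1$sex <- factor("mare", levels = c("gelding", "mare"))
  expect_error(fit_model1(b$usage, metas1), "sex")
  metas2 <- b$metas[b$metas$horse_id %in% c(1:4, 5), ]
  expect_error(fit_model1(b$usage[b$usage$horse_id %in% c(1:4, 5), ], metas2),
               ">= 2 animals")
})

test_that("AICc penalises beyond AIC and is refused for tiny n", {
  set.seed(1)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  fit <- lm(y ~ x, data = d)
  expect_gt(aicc(fit), AIC(fit))
  expect_error(aicc(lm(y ~ x, data = d[1:4, ])), "AICc undefined")
})

test_that("forward selection stops at the intercept for null data", {
  hits <- 0L
  for (rep in 1:20) {
    set.seed(300 + rep)
    d <- data.frame(y = rnorm(40),
                    g = factor(sample(letters[1:3], 40, replace = TRUE)))
    sel <- stepwise_select(d, "y", c("g"))
    if (length(sel$terms) == 0) hits <- hits + 1L
  }
  expect_gte(hits, 18)  # >= 90% of replicates
})

test_that("a strong day effect is selected first, then selection stops", {
  set.seed(9)
  d <- expand.grid(day = factor(1:6), rep = 1:10)
  d$noisefac <- factor(sample(letters[1:2], nrow(d), replace = TRUE))
  d$y <- as.numeric(d$day) * 3 + rnorm(nrow(d))
  sel <- stepwise_select(d, "y", c("noisefac", "day"))
  expect_equal(sel$terms[1], "day")
  tr <- sel$trace
  expect_true(all(diff(tr$aicc[tr$added]) < 0))

  # a single improving candidate finishes in exactly one round
  sel1 <- stepwise_select(d, "y", "day")
  expect_equal(sel1$terms, "day")
  expect_equal(max(sel1$trace$round), 1L)
})

test_that("stepwise selection works with a random animal term (ML fits)", {
  b <- balanced_usage(n_days = 4, sd = 1, day_effect = c(0, 6, -6, 3))
  d <- merge(b$usage, b$metas, by = "horse_id")
  d$fday <- factor(d$day)
  d$animal <- factor(d$horse_id)
  sel <- stepwise_select(d, "squares_per_hour", c("fday", "sex", "breed"),
                         random = "(1 | animal)")
  expect_true("fday" %in% sel$terms)
  expect_equal(sel$terms[1], "fday")
})

test_that("Bonferroni adjustment multiplies by the pair count and caps at 1", {
  set.seed(5)
  d <- data.frame(g = factor(rep(letters[1:4], each = 10)),
                  y = rnorm(40) + rep(c(0, 0.5, 0, 0.2), each = 10))
  fit <- lm(y ~ g, data = d)
  r <- lsm_with_bonferroni(fit, "g")
  expect_equal(r$n_comparisons, choose(4, 2))
  expect_equal(r$bonferroni_multiplier, 6)
  raw <- as.data.frame(emmeans::contrast(emmeans::emmeans(fit, "g"),
                                         method = "pairwise", adjust = "none"))
  expect_equal(r$pairs$p_adj, pmin(1, raw$p.value * 6), tolerance = 1e-12)
  # adjusted significant set is a subset of the unadjusted one
  expect_true(all(!r$pairs$significant | (raw$p.value < 0.05)))

  # balanced one-way: LSMs equal group means
  expect_equal(r$lsm$lsm, as.vector(tapply(d$y, d$g, mean)[r$lsm$level]))

  # two-level factor: single comparison, multiplier 1
  d2 <- data.frame(g = factor(rep(c("a", "b"), each = 6)), y = rnorm(12))
  r2 <- lsm_with_bonferroni(lm(y ~ g, data = d2), "g")
  expect_equal(r2$bonferroni_multiplier, 1)
  raw2 <- as.data.frame(emmeans::contrast(emmeans::emmeans(
    lm(y ~ g, data = d2), "g"), method = "pairwise", adjust = "none"))
  expect_equal(r2$pairs$p_adj, raw2$p.value)
})

test_that("location model recovers constant location frequencies exactly", {
  # two locations with constant frequencies across days -> LSMs equal them
  freqs <- tibble::tibble(
    day = rep(1:5, each = 2),
    date = as.character(rep(1:5, each = 2)),
    row = rep(c(1L, 2L), 5), col = rep(c(1L, 2L), 5),
    n_fixes = 100L,
    frequency = rep(c(30, 70), 5),
    location = rep(c("LH_1", "PADDOCK"), 5))
  suppressWarnings(f <- fit_model2(freqs))
  lsm <- f$lsm_location$lsm
  expect_equal(lsm$lsm[lsm$level == "LH_1"], 30, tolerance = 1e-10)
  expect_equal(lsm$lsm[lsm$level == "PADDOCK"], 70, tolerance = 1e-10)
  w <- testthat::capture_warnings(fit_model2(freqs))
  expect_true(any(grepl("empty location", w)))
})

test_that("additive day + location truth is recovered within Monte-Carlo error", {
  set.seed(31)
  days <- 1:12
  locs <- c("FS_1", "LH_1", "RF_1", "PADDOCK")
  loc_eff <- c(FS_1 = 0.12, LH_1 = 0.08, RF_1 = 0.05, PADDOCK = 0.02)
  day_eff <- rnorm(12, 0, 0.01)
  d <- expand.grid(day = days, location = locs, sq = 1:6)
  d$frequency <- 0.05 + loc_eff[as.character(d$location)] + day_eff[d$day] +
    rnorm(nrow(d), 0, 0.005)
  freqs <- tibble::tibble(day = d$day, date = as.character(d$day),
                          row = d$sq, col = match(d$location, locs),
                          n_fixes = 1L, frequency = d$frequency,
                          location = as.character(d$location))
  suppressWarnings(f <- fit_model2(freqs))
  lsm <- f$lsm_location$lsm
  est_gap <- lsm$lsm[lsm$level == "FS_1"] - lsm$lsm[lsm$level == "PADDOCK"]
  expect_equal(est_gap, unname(loc_eff["FS_1"] - loc_eff["PADDOCK"]),
               tolerance = 0.01)
  expect_true(f$anova["location", "Pr(>F)"] < 0.001)
})
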