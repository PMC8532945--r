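# Model 1: squares/h ~ breed + sex + day + age, random animal (nested in
# breed by construction: every animal belongs to one breed). Model 2:
# square-day frequency ~ day + location. Plus AICc/BIC forward selection
# and Bonferroni-adjusted least-square-mean comparisons.

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` with `k` counting all estimated
#' parameters including variance components. Undefined (error) when
#' `n <= k + 1`.
#'
#' @param fit A fitted model with `logLik` method.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n <= k + 1)
    stop("AICc undefined: n = ", n, " <= k + 1 = ", k + 1)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

excess_kurtosis <- function(x) e1071::kurtosis(x, type = 2)

check_factor_rank <- function(data, terms) {
  for (tm in terms) {
    if (!is.factor(data[[tm]])) next
    if (nlevels(droplevels(data[[tm]])) < 2)
      stop("design is rank deficient: term '", tm,
           "' has a single observed level and is aliased with the intercept")
  }
}

#' Fit the squares-per-hour mixed model
#'
#' REML fit of
#' `squares_per_hour ~ breed + sex + day + age + (1 | animal)`,
#' with day as a factor and the animal intercept as the random effect
#' (animals are nested in breed since each belongs to exactly one).
#' Least-square means are computed at equal factor-level weights with the
#' age covariate at its observed mean; per-animal effects are BLUPs.
#'
#' @param usage Tibble from [horse_day_usage()] (one variant); only rows
#'   with `included` are used.
#' @param metas Tibble from [horse_metas()].
#' @param df_method Degrees-of-freedom method for LSM tests:
#'   `"asymptotic"` (default) or `"satterthwaite"`.
#' @return Object of class `model1_fit`: the `lmerMod` fit plus extracted
#'   `age_slope` (estimate, se, p), `sigma_a2`, `sigma_e2`, `blups`,
#'   `lsm_breed`, `lsm_sex`, `anova` (Satterthwaite F-tests), `aicc`,
#'   `bic`, `residual_kurtosis`, and `n_obs`.
#' @export
fit_model1 <- function(usage, metas, df_method = c("asymptotic",
                                                   "satterthwaite")) {
  df_method <- match.arg(df_method)
  data <- merge(usage[usage$included & !is.na(usage$squares_per_hour), ],
                metas, by = "horse_id")
  data$fday <- factor(data$day)
  data$animal <- factor(data$horse_id)
  data$breed <- droplevels(factor(data$breed))
  data$sex <- droplevels(factor(data$sex))
  check_factor_rank(data, c("breed", "sex", "fday"))
  tab <- table(unique(data[, c("animal", "breed")])$breed)
  if (any(tab < 2))
    stop("need >= 2 animals per represented breed level; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  fit <- lmerTest::lmer(
    squares_per_hour ~ breed + sex + fday + age + (1 | animal),
    data = data, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_a2 <- vc$vcov[vc$grp == "animal"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  ct <- stats::coef(summary(fit))
  re <- lme4::ranef(fit)$animal
  blups <- tibble::tibble(horse_id = as.integer(rownames(re)),
                          blup = re[, 1])
  an <- stats::anova(fit)  # lmerTest Satterthwaite type III
  res <- structure(list(
    fit = fit, data = data,
    age_slope = c(estimate = unname(ct["age", "Estimate"]),
                  se = unname(ct["age", "Std. Error"]),
                  p = unname(ct["age", "Pr(>|t|)"])),
    sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
    blups = blups,
    lsm_breed = lsm_with_bonferroni(fit, "breed", df_method = df_method),
    lsm_sex = lsm_with_bonferroni(fit, "sex", df_method = df_method),
    anova = an,
    aicc = aicc(fit), bic = stats::BIC(fit),
    residual_kurtosis = excess_kurtosis(stats::residuals(fit)),
    n_obs = nrow(data)
  ), class = "model1_fit")
  res
}

#' @export
print.model1_fit <- function(x, ...) {
  cat("<model1_fit> squares/h ~ breed + sex + day + age + (1|animal)\n")
  cat(sprintf("  n = %d horse-days, sigma_a2 = %.2f, sigma_e2 = %.2f\n",
              x$n_obs, x$sigma_a2, x$sigma_e2))
  cat(sprintf("  age slope b = %.3f +/- %.3f (p = %.3g)\n",
              x$age_slope["estimate"], x$age_slope["se"], x$age_slope["p"]))
  cat(sprintf("  AICc = %.1f, BIC = %.1f\n", x$aicc, x$bic))
  invisible(x)
}

#' Least-square means with Bonferroni-adjusted pairwise comparisons
#'
#' LSMs of a factor at equal level weights (other factors averaged, the
#' covariate at its mean), with all pairwise differences tested and raw
#' p-values multiplied by the number of pairs (capped at 1); significance
#' at p < 0.05.
#'
#' @param fit A fitted `lm` or `lmerMod` model.
#' @param factor_name Name of a factor in the model.
#' @param df_method Degrees of freedom for mixed models: `"asymptotic"`
#'   (default) or `"satterthwaite"`.
#' @return List with `lsm` (tibble: level, lsm, se), `pairs` (tibble:
#'   contrast, estimate, se, p_adj, significant), `n_comparisons`, and
#'   `bonferroni_multiplier`.
#' @export
lsm_with_bonferroni <- function(fit, factor_name,
                                df_method = c("asymptotic",
                                              "satterthwaite")) {
  df_method <- match.arg(df_method)
  emm <- emmeans::emmeans(fit, specs = factor_name, lmer.df = df_method)
  s <- as.data.frame(emm)
  lsm <- tibble::tibble(level = as.character(s[[1]]), lsm = s$emmean,
                        se = s$SE)
  k <- nrow(lsm)
  if (k < 2)
    return(list(lsm = lsm,
                pairs = tibble::tibble(contrast = character(),
                                       estimate = double(), se = double(),
                                       p_adj = double(),
                                       significant = logical()),
                n_comparisons = 0L, bonferroni_multiplier = 1))
  pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "bonferroni"))
  pairs <- tibble::tibble(contrast = as.character(pr$contrast),
                          estimate = pr$estimate, se = pr$SE,
                          p_adj = pr$p.value,
                          significant = pr$p.value < 0.05)
  list(lsm = lsm, pairs = pairs,
       n_comparisons = nrow(pairs),
       bonferroni_multiplier = nrow(pairs))
}

#' Forward stepwise selection by AICc
#'
#' Starting from the intercept (plus any random term), repeatedly adds the
#' candidate fixed effect with the smallest AICc; stops when no addition
#' lowers AICc. Comparisons use maximum-likelihood fits (not REML), since
#' fixed-effect structures differ between candidates; BIC is reported
#' alongside. A candidate whose fit would make AICc undefined
#' (`n <= k + 1`) is refused with an error.
#'
#' @param data Data frame with the response and candidate columns.
#' @param response Response column name.
#' @param candidates Character vector of candidate fixed-effect terms.
#' @param random Optional random-effects term, e.g. `"(1 | animal)"`; when
#'   present candidates are compared with `lme4::lmer` ML fits.
#' @return List with `terms` (chosen, in order), `formula`, and `trace`
#'   (tibble: round, term, aicc, bic, added).
#' @export
stepwise_select <- function(data, response, candidates, random = NULL) {
  stopifnot(length(candidates) > 0)
  fit_ml <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    if (!is.null(random)) {
      f <- stats::as.formula(paste(response, "~", rhs, "+", random))
      lme4::lmer(f, data = data, REML = FALSE)
    } else {
      stats::lm(stats::as.formula(paste(response, "~", rhs)), data = data)
    }
  }
  chosen <- character()
  cur <- fit_ml(chosen)
  cur_aicc <- aicc(cur)
  trace <- list(tibble::tibble(round = 0L, term = "(intercept)",
                               aicc = cur_aicc, bic = stats::BIC(cur),
                               added = TRUE))
  remaining <- candidates
  round <- 1L
  while (length(remaining)) {
    scores <- vapply(remaining, function(tm) {
      f <- fit_ml(c(chosen, tm))
      c(aicc = aicc(f), bic = stats::BIC(f))
    }, c(aicc = 0, bic = 0))
    best <- which.min(scores["aicc", ])
    trace[[length(trace) + 1]] <-
      tibble::tibble(round = round, term = remaining[best],
                     aicc = scores["aicc", best], bic = scores["bic", best],
                     added = scores["aicc", best] < cur_aicc)
    if (scores["aicc", best] >= cur_aicc) break
    chosen <- c(chosen, remaining[best])
    cur_aicc <- scores["aicc", best]
    remaining <- remaining[-best]
    round <- round + 1L
  }
  rhs <- if (length(chosen)) paste(chosen, collapse = " + ") else "1"
  if (!is.null(random)) rhs <- paste(rhs, "+", random)
  list(terms = chosen,
       formula = stats::as.formula(paste(response, "~", rhs)),
       trace = do.call(rbind, trace))
}

#' Fit the square-frequency location model
#'
#' Ordinary least squares of
#' `frequency ~ day + location` on the visited (square, day) rows, with
#' day and location as factors. Location LSMs summarise resource usage;
#' residual excess kurtosis is reported (the with-pasture variant is
#' expected to be much more leptokurtic than paddock-only). Empty location
#' levels are dropped with a warning.
#'
#' @param frequencies Tibble from [square_frequencies()].
#' @return Object of class `model2_fit`: the `lm` fit, `lsm_location`,
#'   `lsm_day` summary range, `anova` p-values, `aicc`, `bic`, and
#'   `residual_kurtosis`.
#' @export
fit_model2 <- function(frequencies) {
  data <- data.frame(frequency = frequencies$frequency,
                     fday = factor(frequencies$day),
                     location = factor(frequencies$location,
                                       levels = location_labels()))
  empty <- setdiff(levels(data$location), unique(as.character(data$location)))
  if (length(empty)) {
    warning("dropping empty location level(s): ",
            paste(empty, collapse = ", "))
    data$location <- droplevels(data$location)
  }
  check_factor_rank(data, c("fday", "location"))
  fit <- stats::lm(frequency ~ fday + location, data = data)
  an <- stats::anova(fit)
  structure(list(
    fit = fit, data = data,
    lsm_location = lsm_with_bonferroni(fit, "location"),
    anova = an,
    aicc = aicc(fit), bic = stats::BIC(fit),
    residual_kurtosis = excess_kurtosis(stats::residuals(fit)),
    n_obs = nrow(data)
  ), class = "model2_fit")
}

#' @export
print.model2_fit <- function(x, ...) {
  cat("<model2_fit> frequency ~ day + location\n")
  cat(sprintf("  n = %d square-days, residual excess kurtosis = %.2f\n",
              x$n_obs, x$residual_kurtosis))
  top <- x$lsm_location$lsm[order(-x$lsm_location$lsm$lsm), ][1:3, ]
  cat("  top locations:",
      paste(sprintf("%s=%.3f%%", top$level, top$lsm), collapse = ", "), "\n")
  invisible(x)
}

#' One parameter-recovery replicate
#'
#' Simulates a scaled study (default 20 horses, 60 days with a
#' proportional summer share), computes the with-pasture usage table, fits
#' the squares-per-hour mixed model and compares the fit with the
#' simulator's ground truth: the sign and size of the age slope and the
#' Spearman correlation between animal BLUPs and the true per-horse
#' effects.
#'
#' @param seed Seed for this replicate (metadata and trajectories).
#' @param n_horses,n_days,summer_days Study dimensions.
#' @param layout A [farm_layout()]; defaults to [example_layout()] with a
#'   matching pasture calendar.
#' @param cfg_args Named list of [sim_config()] overrides.
#' @return List: `age_slope` (estimate, se, p), `true_age_slope`,
#'   `blup_spearman`, `pairs` (tibble of per-horse BLUP and true effect,
#'   for pooling across replicates), `sigma_a2`, `sigma_e2`, `mean_sph`,
#'   `sd_sph`, `n_horse_days`.
#' @export
recovery_replicate <- function(seed, n_horses = 20, n_days = 60,
                               summer_days = round(n_days * 159 / 227),
                               layout = example_layout(
                                 n_days = n_days, summer_days = summer_days),
                               cfg_args = list()) {
  metas <- horse_metas(n_horses, n_days = n_days, seed = seed)
  cfg <- do.call(sim_config, c(list(n_horses = n_horses, n_days = n_days,
                                    summer_days = summer_days,
                                    rng_seed = seed), cfg_args))
  r <- simulate_study_usage(metas, layout, cfg)
  f <- fit_model1(r$usage, metas)
  j <- merge(f$blups, r$truth$animal_effects, by = "horse_id")
  inc <- r$usage$included
  list(age_slope = f$age_slope,
       true_age_slope = cfg$age_slope,
       blup_spearman = stats::cor(j$blup, j$animal_effect,
                                  method = "spearman"),
       pairs = tibble::tibble(horse_id = j$horse_id, blup = j$blup,
                              animal_effect = j$animal_effect),
       sigma_a2 = f$sigma_a2, sigma_e2 = f$sigma_e2,
       mean_sph = mean(r$usage$squares_per_hour[inc]),
       sd_sph = stats::sd(r$usage$squares_per_hour[inc]),
       n_horse_days = sum(inc))
}
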