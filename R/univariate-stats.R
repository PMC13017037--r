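#' One-sample t-test against a reference value
#'
#' Classic two-sided one-sample t statistic with `df = n - 1`. Degenerate
#' zero-variance input is reported rather than erroring: `t = 0, p = 1`
#' when the common value equals `mu0`, otherwise an infinite statistic with
#' `p = 0`.
#'
#' @param values Numeric vector (NAs dropped; >= 2 values required).
#' @param mu0 Null value (e.g. the chance level of the score).
#' @param alternative Passed to [stats::t.test()].
#' @return A tibble: `estimate`, `statistic`, `df`, `p_value`, `conf_low`,
#'   `conf_high`.
#' @export
one_sample_t <- function(values, mu0 = 0, alternative = "two.sided") {
  x <- values[!is.na(values)]
  if (length(x) < 2) {
    stop_traitnet("one_sample_t: need >= 2 non-missing values")
  }
  if (sd(x) == 0) {
    inf_t <- if (mean(x) == mu0) 0 else sign(mean(x) - mu0) * Inf
    return(tibble::tibble(
      estimate = mean(x), statistic = inf_t, df = length(x) - 1,
      p_value = if (mean(x) == mu0) 1 else 0,
      conf_low = mean(x), conf_high = mean(x)
    ))
  }
  fit <- t.test(x, mu = mu0, alternative = alternative)
  tibble::tibble(
    estimate = unname(fit$estimate),
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    conf_low = fit$conf.int[1],
    conf_high = fit$conf.int[2]
  )
}

#' Paired-samples t-test
#'
#' One-sample t-test on the within-pair differences `x - y`; incomplete
#' pairs are dropped. Antisymmetric: swapping `x` and `y` flips the sign of
#' the statistic.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A tibble as in [one_sample_t()] (`estimate` is the mean
#'   difference).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    stop_traitnet("paired_t: x and y must have equal length")
  }
  ok <- complete.cases(x, y)
  if (sum(ok) < 2) {
    stop_traitnet("paired_t: need >= 2 complete pairs")
  }
  one_sample_t(x[ok] - y[ok], mu0 = 0)
}

#' Homogeneity of variances (Brown-Forsythe / Levene)
#'
#' Levene's test on absolute deviations from the group medians (the robust
#' Brown-Forsythe centering), via [car::leveneTest()].
#'
#' @param x,y Numeric vectors (the two groups; NAs dropped).
#' @return A tibble: `statistic` (the F/W value), `df1`, `df2`, `p_value`.
#' @export
variance_homogeneity <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop_traitnet("variance_homogeneity: need >= 2 values per group")
  }
  values <- c(x, y)
  group <- factor(rep(c("x", "y"), c(length(x), length(y))))
  fit <- car::leveneTest(values, group, center = median)
  tibble::tibble(
    statistic = fit[1, "F value"],
    df1 = fit[1, "Df"], df2 = fit[2, "Df"],
    p_value = fit[1, "Pr(>F)"]
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average-rank tie handling; two-sided p via the asymptotic
#' t-approximation. Constant input gives an undefined correlation, returned
#' missing with a warning.
#'
#' @param x,y Numeric vectors; >= 4 complete pairs required.
#' @return A tibble: `rho`, `n`, `p_value`.
#' @export
spearman <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 4) {
    stop_traitnet("spearman: need >= 4 complete pairs")
  }
  x <- x[ok]
  y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("spearman: constant input; correlation undefined", call. = FALSE)
    return(tibble::tibble(rho = NA_real_, n = length(x), p_value = NA_real_))
  }
  fit <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(
    rho = unname(fit$estimate), n = length(x), p_value = fit$p.value
  )
}

#' Exact binomial test with Clopper-Pearson interval
#'
#' @param successes,trials Counts with `0 <= successes <= trials`.
#' @param p0 Null success probability (default 0.5).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`; the
#'   first-day memory check against chance is one-sided (`"greater"`).
#' @return A tibble: `estimate`, `p_value`, `ci_low`, `ci_high`.
#' @export
exact_binomial <- function(successes, trials, p0 = 0.5,
                           alternative = "two.sided") {
  fit <- binom.test(successes, trials, p = p0, alternative = alternative)
  tibble::tibble(
    estimate = unname(fit$estimate),
    p_value = fit$p.value,
    ci_low = fit$conf.int[1],
    ci_high = fit$conf.int[2]
  )
}

#' Repeatability (intraclass correlation) with parametric bootstrap
#'
#' Fits the one-way random-intercept model `value = mu + subject + error`
#' and returns `R = sigma2_subject / (sigma2_subject + sigma2_residual)`.
#' For balanced data the REML variance components have the closed
#' ANOVA form (`sigma2_res = MSW`, `sigma2_subj = (MSB - MSW) / k`,
#' truncated at zero), which also makes the parametric bootstrap cheap;
#' unbalanced data fall back to [lme4::lmer()]. The confidence interval is
#' the percentile interval of `R` over `n_boot` simulate-and-refit draws
#' from the fitted model; the p-value is a likelihood-ratio test of the
#' subject variance against the intercept-only model with the conventional
#' 0.5 * chi-square(1) boundary correction.
#'
#' @param values Numeric vector of trial scores.
#' @param subject Subject labels, same length.
#' @param n_boot Parametric bootstrap draws (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param ci_level Interval coverage (default 0.95).
#' @return A `repeatability_fit` object; see [tidy()] / [glance()].
#' @export
repeatability <- function(values, subject, n_boot = 1000, seed = NULL,
                          ci_level = 0.95) {
  ok <- !is.na(values) & !is.na(subject)
  values <- values[ok]
  subject <- factor(subject[ok])
  counts <- table(subject)
  if (length(counts) < 2 || sum(counts >= 2) < 2) {
    stop_traitnet("repeatability: need >= 2 subjects with >= 2 trials each")
  }
  if (all(counts < 2)) {
    stop_traitnet("repeatability: undefined with a single trial per subject")
  }
  balanced <- length(unique(counts)) == 1
  comp <- if (balanced) {
    anova_components(values, subject)
  } else {
    lmm_components(values, subject)
  }
  R <- icc_from(comp)

  boots <- numeric(0)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      if (balanced) {
        k <- unname(counts[1])
        n_s <- length(counts)
        vapply(seq_len(n_boot), function(b) {
          subj_eff <- rnorm(n_s, 0, sqrt(comp$sigma2_subject))
          sim <- matrix(
            rnorm(n_s * k, mean = comp$mu + subj_eff,
              sd = sqrt(comp$sigma2_residual)
            ),
            n_s, k
          )
          icc_from(anova_components(
            as.vector(sim), factor(rep(seq_len(n_s), k))
          ))
        }, numeric(1))
      } else {
        vapply(seq_len(n_boot), function(b) {
          subj_eff <- rnorm(length(counts), 0, sqrt(comp$sigma2_subject))
          sim <- comp$mu + subj_eff[as.integer(subject)] +
            rnorm(length(values), 0, sqrt(comp$sigma2_residual))
          icc_from(lmm_components(sim, subject))
        }, numeric(1))
      }
    })
  }
  alpha <- (1 - ci_level) / 2
  ci <- if (length(boots)) {
    unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  } else {
    c(NA_real_, NA_real_)
  }
  p <- repeatability_lrt(values, subject)
  structure(
    list(
      R = R, ci_low = ci[1], ci_high = ci[2], p_value = p,
      sigma2_subject = comp$sigma2_subject,
      sigma2_residual = comp$sigma2_residual,
      n_boot = n_boot, n_subjects = length(counts),
      boots = boots, seed = seed, ci_level = ci_level
    ),
    class = "repeatability_fit"
  )
}

anova_components <- function(values, subject) {
  k <- unname(table(subject)[1])
  means <- tapply(values, subject, mean)
  grand <- mean(values)
  n_s <- length(means)
  msb <- k * sum((means - grand)^2) / (n_s - 1)
  msw <- if (k > 1) {
    sum((values - means[as.integer(subject)])^2) / (n_s * (k - 1))
  } else {
    0
  }
  list(
    mu = grand,
    sigma2_subject = max(0, (msb - msw) / k),
    sigma2_residual = msw
  )
}

lmm_components <- function(values, subject) {
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(values ~ 1 + (1 | subject))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(
    mu = unname(lme4::fixef(fit)[1]),
    sigma2_subject = vc$vcov[vc$grp == "subject"],
    sigma2_residual = vc$vcov[vc$grp == "Residual"]
  )
}

icc_from <- function(comp) {
  tot <- comp$sigma2_subject + comp$sigma2_residual
  if (tot <= 0) {
    return(0)
  }
  comp$sigma2_subject / tot
}

repeatability_lrt <- function(values, subject) {
  ll1 <- tryCatch(
    as.numeric(logLik(suppressMessages(suppressWarnings(
      lme4::lmer(values ~ 1 + (1 | subject), REML = FALSE)
    )))),
    error = function(e) NA_real_
  )
  if (is.na(ll1)) {
    return(NA_real_)
  }
  ll0 <- as.numeric(logLik(lm(values ~ 1)))
  lrt <- max(0, 2 * (ll1 - ll0))
  0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' @export
print.repeatability_fit <- function(x, ...) {
  cat(sprintf(
    "<repeatability_fit> R = %.3f [%.3f; %.3f], P = %.4g (%d bootstrap draws)\n",
    x$R, x$ci_low, x$ci_high, x$p_value, x$n_boot
  ))
  invisible(x)
}

#' @export
tidy.repeatability_fit <- function(x, ...) {
  tibble::tibble(
    term = "subject", R = x$R, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value
  )
}

#' @export
glance.repeatability_fit <- function(x, ...) {
  tibble::tibble(
    R = x$R, ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
    sigma2_subject = x$sigma2_subject,
    sigma2_residual = x$sigma2_residual,
    n_subjects = x$n_subjects, n_boot = x$n_boot
  )
}

#' Grouped-binomial learning-curve regression
#'
#' Models the daily probability of an error choice with a binomial GLMM:
#' errors and correct choices per day are grouped per subject
#' (`cbind(errors, correct) ~ day + (1 | subject)` via [lme4::glmer()]). A
#' negative day slope on the log-odds-of-error scale means the cohort
#' learns. The day effect is tested with a likelihood-ratio test against
#' the intercept-only GLMM.
#'
#' @param daily_counts A tibble with columns `subject_id`, `day`,
#'   `n_correct`, `n_trials` (see [maze_daily_counts()]).
#' @return A `learning_curve_fit` with `beta` (day slope), `chi_square`,
#'   `p_value`, and the subject intercept variance.
#' @export
learning_curve_fit <- function(daily_counts) {
  req <- c("subject_id", "day", "n_correct", "n_trials")
  if (!all(req %in% names(daily_counts))) {
    stop_traitnet(
      "daily_counts needs columns ", paste(req, collapse = ", ")
    )
  }
  d <- dplyr::filter(daily_counts, !is.na(.data$n_correct))
  if (dplyr::n_distinct(d$day) < 2 || dplyr::n_distinct(d$subject_id) < 2) {
    stop_traitnet("learning_curve_fit: need >= 2 days and >= 2 subjects")
  }
  errors <- d$n_trials - d$n_correct
  separation <- sum(errors) == 0 || sum(d$n_correct) == 0
  if (separation) {
    warning(
      "learning_curve_fit: all-correct or all-error data; estimates are degenerate",
      call. = FALSE
    )
  }
  dat <- data.frame(
    subject = factor(d$subject_id), day = d$day,
    errors = errors, correct = d$n_correct
  )
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(cbind(errors, correct) ~ day + (1 | subject),
      data = dat, family = stats::binomial()
    )
  ))
  fit0 <- suppressMessages(suppressWarnings(
    lme4::glmer(cbind(errors, correct) ~ 1 + (1 | subject),
      data = dat, family = stats::binomial()
    )
  ))
  chi <- max(0, 2 * (as.numeric(logLik(fit)) - as.numeric(logLik(fit0))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      beta = unname(lme4::fixef(fit)["day"]),
      intercept = unname(lme4::fixef(fit)["(Intercept)"]),
      chi_square = chi,
      p_value = pchisq(chi, df = 1, lower.tail = FALSE),
      sigma2_subject = vc$vcov[1],
      separation = separation,
      n_subjects = dplyr::n_distinct(d$subject_id),
      n_days = dplyr::n_distinct(d$day)
    ),
    class = "learning_curve_fit"
  )
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<learning_curve_fit> beta = %.3f (log-odds of error per day), chi2(1) = %.3f, P = %.4g\n",
    x$beta, x$chi_square, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.learning_curve_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "day"),
    estimate = c(x$intercept, x$beta)
  )
}

#' @export
glance.learning_curve_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, chi_square = x$chi_square, p_value = x$p_value,
    sigma2_subject = x$sigma2_subject,
    n_subjects = x$n_subjects, n_days = x$n_days
  )
}

#' Daily correct counts of one maze phase
#'
#' @param cohort A `raw_cohort`.
#' @param phase `"learning"`, `"reversal"` or `"memory"`.
#' @return A tibble `subject_id`, `day`, `n_correct`, `n_trials`, the input
#'   shape expected by [learning_curve_fit()].
#' @export
maze_daily_counts <- function(cohort,
                              phase = c("learning", "reversal", "memory")) {
  phase <- match.arg(phase)
  cohort$maze |>
    dplyr::filter(.data$phase == !!phase) |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(
      n_correct = sum(.data$correct), n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' One-sample trait battery against chance levels
#'
#' Runs the standard one-sample t-tests of a scored trait table: zone
#' scores against their chance levels (thigmotaxis 40%, scototaxis 50%,
#' sociability 50%), lateralization indices against 0, and the flexibility
#' and memory indices against 0.
#'
#' @param trait_table A [build_trait_table()] result.
#' @param thigmotaxis_chance Chance level for thigmotaxis (default the 40 cm
#'   arena with a 4.5 cm band, which rounds to 40).
#' @return A tidy tibble: `trait`, `null_value`, `estimate`, `statistic`,
#'   `df`, `p_value`.
#' @export
univariate_battery <- function(trait_table,
                               thigmotaxis_chance = chance_level(
                                 "square_band",
                                 side = 40, band = 4.5
                               )) {
  nulls <- c(
    thigmotaxis = thigmotaxis_chance,
    scototaxis = 50, sociability = 50,
    motor_lat_rel = 0, motor_lat_abs = 0,
    visual_lat_rel = 0, visual_lat_abs = 0,
    flexibility = 0, memory = 0
  )
  purrr::map_dfr(names(nulls), function(trait) {
    res <- one_sample_t(trait_table[[trait]], mu0 = nulls[[trait]])
    tibble::tibble(
      trait = trait, null_value = nulls[[trait]],
      estimate = res$estimate, statistic = res$statistic,
      df = res$df, p_value = res$p_value
    )
  })
}

#' Trial-comparison battery for the repeated assays
#'
#' For each repeated behavioral / lateralization score, compares the two
#' trials (paired t-test), checks variance homogeneity (Brown-Forsythe),
#' and estimates repeatability with a parametric bootstrap.
#'
#' @param cohort A `raw_cohort` with two behavior trials.
#' @param n_boot Bootstrap draws for the repeatability interval.
#' @param seed Integer seed.
#' @return A tidy tibble with one row per trait: paired-t and Levene
#'   statistics and the repeatability summary.
#' @export
trial_comparison <- function(cohort, n_boot = 1000, seed = NULL) {
  scores <- trial_level_scores(cohort)
  traits <- unique(scores$trait)
  purrr::map_dfr(traits, function(tr) {
    s <- dplyr::filter(scores, .data$trait == tr)
    wide <- tidyr::pivot_wider(
      s,
      id_cols = "subject_id", names_from = "trial",
      values_from = "score", names_prefix = "t"
    )
    pt <- paired_t(wide$t1, wide$t2)
    lev <- variance_homogeneity(wide$t1, wide$t2)
    rpt <- repeatability(
      s$score, s$subject_id,
      n_boot = n_boot, seed = derive_seed(seed, tr)
    )
    tibble::tibble(
      trait = tr,
      paired_t = pt$statistic, paired_t_p = pt$p_value,
      levene_W = lev$statistic, levene_p = lev$p_value,
      R = rpt$R, R_ci_low = rpt$ci_low, R_ci_high = rpt$ci_high,
      R_p = rpt$p_value
    )
  })
}

# Per-trial scores of the repeated assays, long format.
trial_level_scores <- function(cohort) {
  open <- cohort$open_field |>
    dplyr::transmute(
      .data$subject_id, .data$trial,
      activity = .data$distance_cm,
      thigmotaxis = zone_percentage(.data$time_outer_s, .data$time_total_s)
    )
  scoto <- cohort$scototaxis |>
    dplyr::transmute(
      .data$subject_id, .data$trial,
      scototaxis = zone_percentage(.data$time_dark_s, .data$time_total_s)
    )
  socia <- cohort$sociability |>
    dplyr::transmute(
      .data$subject_id, .data$trial,
      sociability = zone_percentage(
        .data$time_near_mirror_s, .data$time_total_s - .data$time_center_s
      )
    )
  lat <- cohort$lateralization |>
    dplyr::mutate(
      lateralization_indices(.data$time_cw_s, .data$time_ccw_s)
    ) |>
    dplyr::transmute(
      .data$subject_id, .data$trial, .data$test,
      rel = .data$relative, abs = .data$absolute
    ) |>
    tidyr::pivot_wider(names_from = "test", values_from = c("rel", "abs"))
  wide <- open |>
    dplyr::left_join(scoto, by = c("subject_id", "trial")) |>
    dplyr::left_join(socia, by = c("subject_id", "trial")) |>
    dplyr::left_join(lat, by = c("subject_id", "trial"))
  names(wide) <- sub("^rel_(motor|visual)$", "\\1_lat_rel", names(wide))
  names(wide) <- sub("^abs_(motor|visual)$", "\\1_lat_abs", names(wide))
  tidyr::pivot_longer(
    wide, -c("subject_id", "trial"),
    names_to = "trait", values_to = "score"
  )
}
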