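#' Monte-Carlo null for criterion-based maze learning
#'
#' Simulates cohorts of random choosers: each subject makes
#' `trials_per_day` independent Bernoulli(0.5) choices per day for `n_days`
#' days and succeeds if any two consecutive days accumulate at least 10
#' correct choices of 12 (the overlapping-window days-to-criterion rule).
#' Each replicate records the percentage of its `n_subjects` subjects that
#' succeed; the distribution of these percentages is the chance-performance
#' null against which an observed number of successful subjects is judged.
#'
#' @param n_subjects Subjects per simulated experiment.
#' @param n_days Day horizon (the maximum days-to-criterion observed in the
#'   real cohort).
#' @param trials_per_day Trials per day (default 6).
#' @param n_replicates Number of simulated experiments (default 10000).
#' @param seed Integer seed.
#' @param window_days Criterion window length (default 2).
#' @return A `null_distribution` object with the per-replicate percentages
#'   and their mean and SD.
#' @examples
#' null <- simulate_chance_experiment(24, 8, n_replicates = 200, seed = 1)
#' glance(null)
#' @export
simulate_chance_experiment <- function(n_subjects, n_days,
                                       trials_per_day = 6,
                                       n_replicates = 10000,
                                       seed = NULL,
                                       window_days = 2) {
  stopifnot(
    is_scalar_number(n_subjects), n_subjects >= 1,
    is_scalar_number(n_days), n_days >= 1,
    is_scalar_number(n_replicates), n_replicates >= 1
  )
  threshold <- criterion_threshold(trials_per_day)
  if (n_days < window_days) {
    warning(
      "criterion needs ", window_days,
      " days; every replicate is 0%",
      call. = FALSE
    )
    pct <- rep(0, n_replicates)
  } else {
    pct <- with_seed(seed, {
      n_tot <- n_subjects * n_replicates
      counts <- matrix(
        rbinom(n_tot * n_days, trials_per_day, 0.5), n_tot, n_days
      )
      success <- rep(FALSE, n_tot)
      for (d in window_days:n_days) {
        win <- rowSums(counts[, (d - window_days + 1):d, drop = FALSE])
        success <- success | (win >= threshold)
      }
      colSums(matrix(success, n_subjects, n_replicates)) / n_subjects * 100
    })
  }
  structure(
    list(
      replicate_percentages = pct,
      mean_percentage = mean(pct),
      sd_percentage = sd(pct),
      n_subjects = as.integer(n_subjects),
      n_days = as.integer(n_days),
      trials_per_day = as.integer(trials_per_day),
      n_replicates = as.integer(n_replicates),
      threshold = threshold,
      window_days = as.integer(window_days),
      seed = seed
    ),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(
    "<null_distribution> ", x$n_replicates, " replicates of ",
    x$n_subjects, " random choosers over ", x$n_days, " days\n",
    sep = ""
  )
  cat(
    "  % reaching criterion: ",
    sprintf("%.2f +/- %.2f", x$mean_percentage, x$sd_percentage), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(
    replicate = seq_along(x$replicate_percentages),
    pct_reaching_criterion = x$replicate_percentages
  )
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(
    mean_percentage = x$mean_percentage,
    sd_percentage = x$sd_percentage,
    n_subjects = x$n_subjects,
    n_days = x$n_days,
    n_replicates = x$n_replicates
  )
}

#' @export
autoplot.null_distribution <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$pct_reaching_criterion)) +
    ggplot2::geom_histogram(binwidth = 100 / object$n_subjects,
      fill = "grey40"
    ) +
    ggplot2::labs(
      x = "% of simulated subjects reaching criterion",
      y = "replicates",
      title = sprintf(
        "Chance null: %d subjects, %d days", object$n_subjects,
        object$n_days
      )
    )
}

#' Monte-Carlo p-value for an observed number of successful subjects
#'
#' `(1 + # replicates with at least as many successes) / (n_replicates +
#' 1)`; the add-one convention never returns zero from a finite run, so an
#' observation beyond every replicate is reported as a bound
#' `< 1 / (n_replicates + 1)`.
#'
#' @param null A [simulate_chance_experiment()] result.
#' @param observed_successes Observed number of subjects reaching criterion,
#'   in `[0, n_subjects]`.
#' @return A tibble with `p_value`, `exceeded` (replicates at or above the
#'   observation) and a display `label`.
#' @export
pvalue_observed <- function(null, observed_successes) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is_scalar_number(observed_successes) ||
    observed_successes < 0 || observed_successes > null$n_subjects) {
    stop_traitnet(
      "observed_successes must lie in [0, ", null$n_subjects, "]"
    )
  }
  obs_pct <- observed_successes / null$n_subjects * 100
  k <- sum(null$replicate_percentages >= obs_pct - 1e-9)
  p <- (1 + k) / (null$n_replicates + 1)
  tibble::tibble(
    observed_successes = observed_successes,
    exceeded = k,
    p_value = p,
    label = if (k == 0) {
      sprintf("< %.3g", 1 / (null$n_replicates + 1))
    } else {
      sprintf("%.4g", p)
    }
  )
}

#' Exact probability that a random chooser reaches the criterion
#'
#' Dynamic program over the previous day's correct count: a subject's day
#' draws are iid Binomial(`trials_per_day`, 1/2); it is absorbed into the
#' success state on the first day `d >= 2` with
#' `count(d-1) + count(d) >= threshold`. This is the closed-form oracle for
#' the Monte-Carlo simulation: the per-replicate percentage is
#' `100 * Binomial(n_subjects, p) / n_subjects` with `p` the value returned
#' here.
#'
#' @param n_days Day horizon (>= 1).
#' @param trials_per_day Trials per day (default 6).
#' @param threshold Two-day sum required (default 10).
#' @return The success probability.
#' @examples
#' exact_criterion_probability(2) # 79/4096
#' @export
exact_criterion_probability <- function(n_days, trials_per_day = 6,
                                        threshold = 10) {
  stopifnot(is_scalar_number(n_days), n_days >= 1)
  pmf <- dbinom(0:trials_per_day, trials_per_day, 0.5)
  if (n_days < 2) {
    return(0)
  }
  state <- pmf # distribution of yesterday's count among the unabsorbed
  for (d in 2:n_days) {
    new_state <- numeric(trials_per_day + 1)
    for (cur in 0:trials_per_day) {
      # yesterday's count s survives alongside today's cur iff s + cur < threshold
      n_surv <- min(trials_per_day + 1, max(0, threshold - cur))
      new_state[cur + 1] <- sum(state[seq_len(n_surv)]) * pmf[cur + 1]
    }
    state <- new_state
  }
  1 - sum(state)
}

#' Goodness-of-fit chi-square for a correct/incorrect split
#'
#' Pearson chi-square of the observed (correct, incorrect) counts against
#' equal expected counts, 1 df, no continuity correction. The conventional
#' criterion-level statistic: 20 correct vs 4 incorrect gives 10.667.
#'
#' @param correct,incorrect Non-negative counts, not both zero.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @examples
#' criterion_chi_square(20, 4)
#' @export
criterion_chi_square <- function(correct, incorrect) {
  if (!is_scalar_number(correct) || !is_scalar_number(incorrect) ||
    correct < 0 || incorrect < 0 || correct + incorrect <= 0) {
    stop_traitnet("counts must be non-negative and not both zero")
  }
  fit <- suppressWarnings(
    chisq.test(c(correct, incorrect), p = c(0.5, 0.5), correct = FALSE)
  )
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value
  )
}
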