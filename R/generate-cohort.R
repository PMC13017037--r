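#' Generate a synthetic raw cohort with known latent trait covariance
#'
#' Draws one latent vector per subject from a multivariate normal with
#' correlation `config$latent_corr` and maps each latent coordinate
#' monotonically to the raw observables of the corresponding assay:
#' durations via logistic squashing to valid fractions of trial time, beats
#' per minute and distances via affine maps clipped at zero, and maze
#' performance by giving each subject a logistic daily probability-of-correct
#' curve whose slope is driven by the subject's maze latent, then sampling
#' Bernoulli choices and truncating each phase at the criterion day.
#' Monotonicity of every map preserves rank correlations, so the Spearman
#' structure of the scored traits recovers the planted latent structure.
#'
#' The three maze latents are oriented so that a larger latent value means a
#' *slower* learner (more days to criterion) in that phase; plant latent
#' correlations on the days scale accordingly.
#'
#' Block-wise missingness is injected afterwards at `config$missing_rate` via
#' [inject_missingness()].
#'
#' @param config A [cohort_config()].
#' @return A `raw_cohort`: a named list of tidy tibbles (`subjects`,
#'   `ventilation`, `open_field`, `scototaxis`, `sociability`,
#'   `lateralization`, `maze`) with the generating config attached as an
#'   attribute.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 6, seed = 1))
#' names(cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop_traitnet("config must be a cohort_config object")
  }
  cohort <- with_seed(config$seed, generate_cohort_impl(config))
  if (config$missing_rate > 0) {
    cohort <- inject_missingness(
      cohort, config$missing_rate,
      seed = derive_seed(config$seed, "missingness")
    )
  }
  cohort
}

generate_cohort_impl <- function(config) {
  n <- config$n_subjects
  k <- length(trait_names())
  mu <- config$trait_means
  sdv <- config$trait_sds
  icc <- config$trial_icc
  n_trials <- config$n_behavior_trials
  trial_min <- 1800 # 30-min assays, scored in seconds

  # latent draw through the eigen square root (tolerates semi-definite input)
  ed <- eigen(config$latent_corr, symmetric = TRUE)
  rot <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), k)
  z <- matrix(rnorm(n * k), n, k) %*% t(rot)

  ids <- sprintf("S%03d", seq_len(n))
  trial_latent <- function(col) {
    sqrt(icc) * z[, col] + sqrt(1 - icc) * rnorm(n)
  }
  squash <- function(zz, mean_pct, sd_pct) {
    p0 <- min(max(mean_pct / 100, 0.02), 0.98)
    b <- (sd_pct / 100) / (p0 * (1 - p0))
    plogis(qlogis(p0) + b * zz)
  }

  # -- morphometrics -------------------------------------------------------
  len1 <- pmax(rnorm(n, 5.82, 0.35), 1)
  growth <- pmax(mu[1] + sdv[1] * z[, 1], -90)
  len2 <- len1 * (1 + growth / 100)
  w1 <- pmax(exp(log(1.82) + 2.9 * log(len1 / 5.82) + rnorm(n, 0, 0.08)), 0.2)
  w2 <- w1 * (len2 / len1)^3 * exp(rnorm(n, 0, 0.05))
  subjects <- tibble::tibble(
    subject_id = ids,
    length_cm_t1 = len1, weight_g_t1 = w1,
    length_cm_t2 = len2, weight_g_t2 = w2
  )

  # -- ventilation ---------------------------------------------------------
  basal_pg <- pmax(mu[2] + sdv[2] * z[, 2], 5)
  basal_bpm <- basal_pg * w1
  stress_pct <- pmax(mu[3] + sdv[3] * z[, 3], -90)
  ventilation <- tibble::tibble(
    subject_id = ids,
    ventilation_stress_bpm = basal_bpm * (1 + stress_pct / 100),
    ventilation_basal_bpm = basal_bpm
  )

  # -- repeated behavioral assays -----------------------------------------
  open_field <- scoto <- socia <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    dist <- pmax(mu[4] + sdv[4] * trial_latent(4), 0)
    outer_frac <- squash(trial_latent(5), mu[5], sdv[5])
    open_field[[t]] <- tibble::tibble(
      subject_id = ids, trial = t,
      distance_cm = dist,
      time_outer_s = trial_min * outer_frac,
      time_total_s = trial_min
    )
    dark_frac <- squash(trial_latent(6), mu[6], sdv[6])
    scoto[[t]] <- tibble::tibble(
      subject_id = ids, trial = t,
      time_dark_s = trial_min * dark_frac,
      time_total_s = trial_min
    )
    center_s <- trial_min * runif(n, 0.15, 0.45)
    near_frac <- squash(trial_latent(7), mu[7], sdv[7])
    socia[[t]] <- tibble::tibble(
      subject_id = ids, trial = t,
      time_near_mirror_s = (trial_min - center_s) * near_frac,
      time_center_s = center_s,
      time_total_s = trial_min
    )
  }

  # -- lateralization ------------------------------------------------------
  # magnitude (absolute index) is a logistic map of the "abs" latent;
  # direction is tanh of the "rel" latent; relative = magnitude * direction,
  # so the absolute score is monotone in its latent given the direction and
  # vice versa. E|tanh(Z)| ~ 0.606 motivates the magnitude rescaling.
  lat <- list()
  for (test in c("motor", "visual")) {
    rel_col <- if (test == "motor") 8L else 10L
    abs_col <- rel_col + 1L
    q <- min(max((mu[abs_col] / 100) / 0.606, 0.02), 0.95)
    a1 <- (sdv[abs_col] / 100) / (q * (1 - q))
    d0 <- atanh(min(max(mu[rel_col] / max(mu[abs_col], 1e-6), -0.9), 0.9))
    for (t in seq_len(n_trials)) {
      magnitude <- 100 * plogis(qlogis(q) + a1 * trial_latent(abs_col))
      direction <- tanh(trial_latent(rel_col) + d0)
      rel <- magnitude * direction
      freeze_s <- trial_min * runif(n, 0.05, 0.2)
      center_s <- trial_min * runif(n, 0.05, 0.2)
      edge_s <- trial_min - freeze_s - center_s
      cw <- edge_s * (1 + rel / 100) / 2
      lat[[paste(test, t)]] <- tibble::tibble(
        subject_id = ids, test = test, trial = t,
        time_cw_s = cw, time_ccw_s = edge_s - cw,
        time_center_s = center_s, time_freeze_s = freeze_s
      )
    }
  }

  # -- maze phases ---------------------------------------------------------
  # P(correct on day d) = plogis(intercept + slope * d); the slope is
  # log-normal in the phase latent with a NEGATIVE loading, so a larger
  # latent gives a flatter curve and more days to criterion. Intercepts:
  # learning starts at chance, reversal below chance (the previously
  # rewarded arm is now wrong), memory above chance (retention).
  phases <- list(
    learning = list(col = 12L, intercept = 0, slope_base = 0.35),
    reversal = list(col = 13L, intercept = -0.5, slope_base = 0.45),
    memory = list(col = 14L, intercept = 0.9, slope_base = 0.45)
  )
  maze <- list()
  for (phase in names(phases)) {
    ph <- phases[[phase]]
    slope <- exp(log(ph$slope_base) - 0.45 * z[, ph$col])
    for (i in seq_len(n)) {
      seqs <- simulate_phase_choices(
        intercept = ph$intercept, slope = slope[i],
        trials_per_day = config$trials_per_day, max_days = config$max_days
      )
      maze[[paste(phase, i)]] <- tibble::tibble(
        subject_id = ids[i], phase = phase,
        day = rep(seq_len(nrow(seqs)), each = config$trials_per_day),
        trial = rep(seq_len(config$trials_per_day), nrow(seqs)),
        correct = as.integer(t(seqs))
      )
    }
  }

  structure(
    list(
      subjects = subjects,
      ventilation = ventilation,
      open_field = dplyr::bind_rows(open_field),
      scototaxis = dplyr::bind_rows(scoto),
      sociability = dplyr::bind_rows(socia),
      lateralization = dplyr::bind_rows(lat),
      maze = dplyr::bind_rows(maze)
    ),
    config = config,
    class = "raw_cohort"
  )
}

# Daily Bernoulli choices for one subject in one phase, truncated on the
# first day the overlapping two-day criterion is met (or at max_days).
simulate_phase_choices <- function(intercept, slope, trials_per_day,
                                   max_days) {
  threshold <- criterion_threshold(trials_per_day)
  rows <- matrix(NA_integer_, max_days, trials_per_day)
  counts <- integer(max_days)
  for (d in seq_len(max_days)) {
    p <- plogis(intercept + slope * d)
    rows[d, ] <- rbinom(trials_per_day, 1, p)
    counts[d] <- sum(rows[d, ])
    if (d >= 2 && counts[d - 1] + counts[d] >= threshold) {
      return(rows[seq_len(d), , drop = FALSE])
    }
  }
  rows
}

# 10-of-12 over two consecutive days at 6 trials/day; scales as 2m - 2 for
# other daily trial counts.
criterion_threshold <- function(trials_per_day) {
  if (trials_per_day == 6) 10L else as.integer(2L * trials_per_day - 2L)
}

#' @export
print.raw_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<raw_cohort>", nrow(x$subjects), "subjects\n")
  cat("  assays:", paste(names(x), collapse = ", "), "\n")
  if (!is.null(cfg)) cat("  seed:", cfg$seed %||% NA, "\n")
  invisible(x)
}

#' Inject block-wise missingness mimicking subject withdrawal
#'
#' Marks whole assay blocks as missing, the way subjects withdrawn from the
#' later tests lose data: a stage-1 withdrawal loses the visual
#' lateralization test and the reversal and memory maze phases; a stage-2
#' withdrawal loses only the memory phase. Withdrawal probabilities are
#' scaled so the expected missing-cell fraction of the scored subjects x 14
#' trait table equals `rate`, with stage-2 withdrawals twice as likely as
#' stage-1. First-timepoint morphometrics are never removed.
#'
#' @param cohort A `raw_cohort`.
#' @param rate Target expected missing-cell fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return The cohort with the affected assay rows removed.
#' @export
inject_missingness <- function(cohort, rate, seed = NULL) {
  if (!inherits(cohort, "raw_cohort")) {
    stop_traitnet("cohort must be a raw_cohort")
  }
  if (!is_scalar_number(rate) || rate < 0 || rate > 1) {
    stop_traitnet("rate must lie in [0, 1]")
  }
  if (rate == 0) {
    return(cohort)
  }
  # stage 1 costs 4 cells of 14 (visual rel/abs, flexibility, memory);
  # stage 2 costs 1 (memory); with q2 = 2 q1 the expected cell fraction is
  # (4 q1 + 2 q1) / 14 = rate, hence q1 = 7 rate / 3.
  q1 <- min(7 * rate / 3, 1)
  q2 <- min(2 * q1, 1 - q1)
  ids <- cohort$subjects$subject_id
  u <- with_seed(seed, runif(length(ids)))
  stage1 <- ids[u < q1]
  stage2 <- ids[u >= q1 & u < q1 + q2]
  if (length(stage1) > 0) {
    cohort$lateralization <- dplyr::filter(
      cohort$lateralization,
      !(.data$subject_id %in% stage1 & .data$test == "visual")
    )
    cohort$maze <- dplyr::filter(
      cohort$maze,
      !(.data$subject_id %in% stage1 &
        .data$phase %in% c("reversal", "memory"))
    )
  }
  if (length(stage2) > 0) {
    cohort$maze <- dplyr::filter(
      cohort$maze,
      !(.data$subject_id %in% stage2 & .data$phase == "memory")
    )
  }
  attr(cohort, "missingness") <- list(
    rate = rate, seed = seed,
    withdrawn_stage1 = stage1, withdrawn_stage2 = stage2
  )
  cohort
}

#' Write or read a raw cohort as tidy delimited-text tables
#'
#' `write_cohort()` writes one tab-separated file per assay plus a JSON
#' manifest holding the generating configuration and seed; `read_cohort()`
#' restores the cohort exactly (numeric values are written with a
#' round-trippable representation).
#'
#' @param cohort A `raw_cohort`.
#' @param dir Directory to write to / read from.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `raw_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "raw_cohort")) {
    stop_traitnet("cohort must be a raw_cohort")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort)) {
    readr::write_tsv(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  cfg <- attr(cohort, "config")
  manifest <- list(tables = names(cohort))
  if (!is.null(cfg)) {
    manifest$config <- unclass(cfg)
    manifest$config$latent_corr <- unname(as.matrix(cfg$latent_corr))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  tables <- lapply(manifest$tables, function(nm) {
    readr::read_tsv(file.path(dir, paste0(nm, ".tsv")),
      show_col_types = FALSE, progress = FALSE
    )
  })
  names(tables) <- manifest$tables
  cohort <- structure(tables, class = "raw_cohort")
  if (!is.null(manifest$config)) {
    cfg <- manifest$config
    attr(cohort, "config") <- cohort_config(
      n_subjects = cfg$n_subjects,
      latent_corr = matrix(unlist(cfg$latent_corr),
        nrow = length(trait_names())
      ),
      trait_means = cfg$trait_means,
      trait_sds = cfg$trait_sds,
      trials_per_day = cfg$trials_per_day,
      max_days = cfg$max_days,
      n_behavior_trials = cfg$n_behavior_trials,
      trial_icc = cfg$trial_icc,
      missing_rate = cfg$missing_rate,
      seed = cfg$seed
    )
  }
  cohort
}
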