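#' Default trait means and spreads for the synthetic cohort
#'
#' Per-trait location and spread on the observable scale used by
#' [generate_cohort()]. The defaults are plausible population summaries for a
#' small cohort of juvenile wild tench: growth as percent length change,
#' basal metabolism as weight-normalized operculum beats (bpm/g), stress
#' metabolism as percent ventilation increase over the basal rate, open-field
#' distance in cm, zone scores in percent, lateralization indices in percent,
#' and the three maze traits (days to criterion and the two derived indices),
#' whose defaults describe the emergent scale of the choice simulation rather
#' than parameters that are imposed directly.
#'
#' @return A tibble with columns `trait`, `mean`, `sd`.
#' @export
default_trait_moments <- function() {
  tibble::tibble(
    trait = trait_names(),
    mean = c(
      5.23, 84.5, 102.68, 4053.14, 78.26, 90.68, 54.94,
      -2.40, 26.15, -1.18, 12.69, 4.83, -0.41, 0.39
    ),
    sd = c(
      4.01, 25.14, 88.54, 2160.74, 18.27, 7.77, 21.45,
      33.93, 21.06, 15.56, 8.68, 2.12, 0.99, 0.34
    )
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every knob of the raw-data generator: cohort size, the latent
#' trait correlation structure, observable-scale locations and spreads,
#' trial/day structure of the maze, between-trial reliability of the repeated
#' assays, and the block-missingness rate.
#'
#' @param n_subjects Number of subjects (>= 3). Default 24.
#' @param latent_corr 14 x 14 correlation matrix over the latent trait
#'   dimensions, ordered as [default_trait_moments()]. Must be symmetric with
#'   unit diagonal and eigenvalues >= -1e-10. Default identity.
#' @param trait_means,trait_sds Numeric vectors of length 14 on the observable
#'   scale; defaults from [default_trait_moments()].
#' @param trials_per_day Maze trials per day (default 6).
#' @param max_days Cap on simulated maze days per phase (default 20).
#' @param n_behavior_trials Repetitions of the behavioral and lateralization
#'   assays (default 2).
#' @param trial_icc Intra-class correlation of repeated behavioral trials on
#'   the latent scale; 1 makes the repeated assays deterministic functions of
#'   the subject latent. Default 0.6.
#' @param missing_rate Expected fraction of missing cells in the scored
#'   subjects x 14 trait table, produced by block-wise dropout
#'   (default 6/336).
#' @param seed Integer seed; every stochastic choice of the generator is a
#'   deterministic function of it.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 24,
                          latent_corr = NULL,
                          trait_means = NULL,
                          trait_sds = NULL,
                          trials_per_day = 6,
                          max_days = 20,
                          n_behavior_trials = 2,
                          trial_icc = 0.6,
                          missing_rate = 6 / 336,
                          seed = 1L) {
  k <- length(trait_names())
  moments <- default_trait_moments()
  if (is.null(latent_corr)) {
    latent_corr <- diag(k)
  }
  latent_corr <- as.matrix(latent_corr)
  if (is.null(trait_means)) trait_means <- moments$mean
  if (is.null(trait_sds)) trait_sds <- moments$sd
  if (length(trait_means) != k || length(trait_sds) != k) {
    stop_traitnet(
      "trait_means and trait_sds must have length ", k,
      " (one entry per trait dimension)"
    )
  }
  if (!is_scalar_number(n_subjects) || n_subjects < 3) {
    stop_traitnet("n_subjects must be a single number >= 3")
  }
  if (!is_scalar_number(missing_rate) || missing_rate < 0 || missing_rate > 1) {
    stop_traitnet("missing_rate must lie in [0, 1]")
  }
  if (!is_scalar_number(trial_icc) || trial_icc < 0 || trial_icc > 1) {
    stop_traitnet("trial_icc must lie in [0, 1]")
  }
  check_latent_corr(latent_corr, k)
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      latent_corr = latent_corr,
      trait_means = as.numeric(trait_means),
      trait_sds = as.numeric(trait_sds),
      trials_per_day = as.integer(trials_per_day),
      max_days = as.integer(max_days),
      n_behavior_trials = as.integer(n_behavior_trials),
      trial_icc = trial_icc,
      missing_rate = missing_rate,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "cohort_config"
  )
}

check_latent_corr <- function(m, k) {
  if (nrow(m) != k || ncol(m) != k) {
    stop_traitnet("latent_corr must be ", k, " x ", k)
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop_traitnet("latent_corr must be symmetric")
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop_traitnet("latent_corr must have unit diagonal")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop_traitnet(
      "latent_corr is not positive semi-definite: smallest eigenvalue ",
      format(min(ev), digits = 6)
    )
  }
  invisible(m)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  subjects:", x$n_subjects, "\n")
  cat(
    "  maze:", x$trials_per_day, "trials/day, up to", x$max_days, "days\n"
  )
  cat("  behavior trials:", x$n_behavior_trials,
      " trial ICC:", x$trial_icc, "\n")
  cat("  missing rate:", signif(x$missing_rate, 4), "\n")
  off <- x$latent_corr[upper.tri(x$latent_corr)]
  cat("  latent correlations: ", sum(off != 0), " nonzero off-diagonal\n",
      sep = ""
  )
  invisible(x)
}
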