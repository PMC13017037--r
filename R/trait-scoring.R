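#' Percent change relative to a baseline
#'
#' `(value - baseline) / baseline * 100`. Used for the growth index (final
#' vs. initial body length) and for stress metabolism (ventilation under
#' stress vs. the basal rate).
#'
#' @param value,baseline Numeric vectors; `baseline` must be positive.
#' @return Percent change, same length as the inputs.
#' @examples
#' percent_change(5.5, 5) # 10
#' @export
percent_change <- function(value, baseline) {
  if (any(baseline <= 0, na.rm = TRUE)) {
    stop_traitnet("percent_change: baseline must be positive")
  }
  (value - baseline) / baseline * 100
}

#' Zone occupancy as a percentage of available time
#'
#' `time_in / denominator * 100`; thigmotaxis and scototaxis pass the total
#' trial time as denominator, sociability passes total minus the time in the
#' central sector. A non-positive denominator gives an undefined score: the
#' cell is returned missing with a warning rather than erroring, so it can
#' feed the imputation stage.
#'
#' @param time_in,denominator Times in seconds, `0 <= time_in <= denominator`.
#' @return Percentage in `[0, 100]` (NA where undefined).
#' @export
zone_percentage <- function(time_in, denominator) {
  out <- rep(NA_real_, length(time_in))
  bad <- !is.na(denominator) & denominator <= 0
  if (any(bad)) {
    warning("zone_percentage: non-positive denominator; score set missing",
      call. = FALSE
    )
  }
  ok <- !bad & !is.na(time_in) & !is.na(denominator)
  if (any(time_in[ok] < 0 | time_in[ok] > denominator[ok])) {
    stop_traitnet("zone_percentage: time_in must lie in [0, denominator]")
  }
  out[ok] <- time_in[ok] / denominator[ok] * 100
  out
}

#' Relative and absolute lateralization indices
#'
#' Relative index: `(cw - ccw) / (cw + ccw) * 100`, in `[-100, 100]`;
#' absolute index: its absolute value, measuring lateralization strength
#' irrespective of direction. Both zero times give an undefined index
#' (missing, with a warning).
#'
#' @param time_cw,time_ccw Non-negative times (s) spent swimming clockwise /
#'   counterclockwise.
#' @return A tibble with columns `relative` and `absolute`.
#' @examples
#' lateralization_indices(300, 100) # relative 50, absolute 50
#' @export
lateralization_indices <- function(time_cw, time_ccw) {
  if (any(time_cw < 0 | time_ccw < 0, na.rm = TRUE)) {
    stop_traitnet("lateralization_indices: times must be non-negative")
  }
  total <- time_cw + time_ccw
  rel <- rep(NA_real_, length(total))
  zero <- !is.na(total) & total == 0
  if (any(zero)) {
    warning(
      "lateralization_indices: zero edge time; index set missing",
      call. = FALSE
    )
  }
  ok <- !zero & !is.na(total)
  rel[ok] <- (time_cw[ok] - time_ccw[ok]) / total[ok] * 100
  tibble::tibble(relative = rel, absolute = abs(rel))
}

#' Weight-normalized basal ventilation
#'
#' Basal operculum beats per minute divided by body weight (bpm/g), the
#' proxy for basal metabolic rate.
#'
#' @param basal_bpm Beats per minute.
#' @param weight Body weight in grams, positive.
#' @return bpm/g.
#' @export
basal_per_gram <- function(basal_bpm, weight) {
  if (any(weight <= 0, na.rm = TRUE)) {
    stop_traitnet("basal_per_gram: weight must be positive")
  }
  basal_bpm / weight
}

#' First day the learning criterion is reached
#'
#' Scans overlapping windows of `window_days` consecutive days and returns
#' the first (1-based) day index `d` whose window sum of daily correct
#' counts reaches `threshold` (default: 10 correct of 12 trials over 2
#' days). Returns `NA` if the criterion is never met. The result is
#' invariant to appending days after the criterion day.
#'
#' @param daily_correct Integer vector of daily correct-choice counts, each
#'   in `[0, trials_per_day]`.
#' @param threshold Window sum required (default 10).
#' @param window_days Window length in days (default 2).
#' @param trials_per_day Trials per day (default 6).
#' @return Integer day index, or `NA_integer_`.
#' @examples
#' days_to_criterion(c(3, 4, 5, 6)) # 4
#' days_to_criterion(c(6, 4)) # 2, the fastest possible
#' @export
days_to_criterion <- function(daily_correct, threshold = 10,
                              window_days = 2, trials_per_day = 6) {
  if (length(daily_correct) == 0) {
    return(NA_integer_)
  }
  if (any(is.na(daily_correct)) ||
    any(daily_correct < 0 | daily_correct > trials_per_day)) {
    stop_traitnet(
      "days_to_criterion: counts must lie in [0, ", trials_per_day, "]"
    )
  }
  n <- length(daily_correct)
  if (n < window_days) {
    return(NA_integer_)
  }
  for (d in window_days:n) {
    if (sum(daily_correct[(d - window_days + 1):d]) >= threshold) {
      return(as.integer(d))
    }
  }
  NA_integer_
}

#' Phase-to-phase performance index
#'
#' `-(days_after - days_before) / days_before`: positive when the later
#' phase was solved faster than the baseline phase. Cognitive flexibility
#' uses reversal days against learning days; the memory index uses memory
#' days against reversal days.
#'
#' @param days_after Days to criterion in the later phase.
#' @param days_before Days to criterion in the baseline phase (>= 1).
#' @return The index (unitless).
#' @examples
#' phase_index(8, 4) # -1: twice as slow
#' phase_index(2, 4) # +0.5: twice as fast
#' @export
phase_index <- function(days_after, days_before) {
  if (any(days_before < 1, na.rm = TRUE)) {
    stop_traitnet("phase_index: baseline days must be >= 1")
  }
  -(days_after - days_before) / days_before
}

#' Chance level of a zone-occupancy score
#'
#' For a square arena of side `side` with an edge band of width `band`, the
#' chance thigmotaxis level is the band area over the total area:
#' `(side^2 - (side - 2 band)^2) / side^2 * 100` (39.94% for a 40 cm arena
#' with a 4.5 cm band, i.e. the usual 40%). Half-split apparatuses
#' (scototaxis, sociability) have a 50% chance level.
#'
#' @param shape `"square_band"` or `"half_split"`.
#' @param side Arena side (cm), for `"square_band"`.
#' @param band Edge band width (cm), `0 <= band <= side / 2`.
#' @return Chance level in percent.
#' @examples
#' chance_level("square_band", side = 40, band = 4.5) # 39.9375
#' @export
chance_level <- function(shape = c("square_band", "half_split"),
                         side = NULL, band = NULL) {
  shape <- match.arg(shape)
  if (shape == "half_split") {
    return(50)
  }
  if (!is_scalar_number(side) || !is_scalar_number(band) ||
    side <= 0 || band < 0 || band > side / 2) {
    stop_traitnet("chance_level: need side > 0 and 0 <= band <= side / 2")
  }
  (side^2 - (side - 2 * band)^2) / side^2 * 100
}

#' Days-to-criterion summary for every maze phase of a cohort
#'
#' @param cohort A `raw_cohort`.
#' @param threshold,window_days Criterion parameters (see
#'   [days_to_criterion()]).
#' @return A tibble with one row per subject x phase: `days_to_criterion`
#'   (NA when the phase is missing or the criterion was never met) and the
#'   daily correct counts as a list column.
#' @export
maze_phase_results <- function(cohort, threshold = NULL, window_days = 2) {
  cfg <- attr(cohort, "config")
  tpd <- cfg$trials_per_day %||% 6L
  threshold <- threshold %||% criterion_threshold(tpd)
  daily <- cohort$maze |>
    dplyr::group_by(.data$subject_id, .data$phase, .data$day) |>
    dplyr::summarise(n_correct = sum(.data$correct), .groups = "drop") |>
    dplyr::arrange(.data$subject_id, .data$phase, .data$day)
  daily |>
    dplyr::group_by(.data$subject_id, .data$phase) |>
    dplyr::summarise(
      days_to_criterion = days_to_criterion(
        .data$n_correct,
        threshold = threshold, window_days = window_days,
        trials_per_day = tpd
      ),
      daily_correct = list(.data$n_correct),
      .groups = "drop"
    )
}

#' Assemble the subjects x traits table
#'
#' Computes all 14 derived trait scores from the raw records: growth (%
#' length change), basal metabolism (bpm/g, normalized by first-timepoint
#' weight), stress metabolism (% ventilation increase), activity (cm),
#' thigmotaxis / scototaxis / sociability (%), relative and absolute motor
#' and visual lateralization (%), spatial learning (days to criterion), and
#' the flexibility and memory indices. Repeated behavioral and
#' lateralization assays are aggregated per `trials` (the absolute
#' lateralization score aggregates the per-trial absolute indices). Missing
#' assay blocks propagate to missing cells.
#'
#' The `stress` and `flexibility` switches swap in the raw control
#' variables: stress-condition bpm instead of the percent index, and raw
#' reversal days instead of the flexibility index. Together with
#' `trials = "first"` they reproduce the robustness (control) analysis.
#'
#' @param cohort A `raw_cohort`.
#' @param trials `"mean"` (average of the repeated trials, default) or
#'   `"first"` (first trial only).
#' @param stress `"index"` (percent increase, default) or `"raw"`
#'   (stress-condition bpm).
#' @param flexibility `"index"` (default) or `"raw"` (reversal days).
#' @return A tibble with `subject_id` plus the 14 trait columns, one row per
#'   subject.
#' @export
build_trait_table <- function(cohort,
                              trials = c("mean", "first"),
                              stress = c("index", "raw"),
                              flexibility = c("index", "raw")) {
  if (!inherits(cohort, "raw_cohort")) {
    stop_traitnet("cohort must be a raw_cohort")
  }
  trials <- match.arg(trials)
  stress <- match.arg(stress)
  flexibility <- match.arg(flexibility)
  if (anyDuplicated(cohort$subjects$subject_id)) {
    stop_traitnet("duplicate subject ids in cohort")
  }
  agg <- function(x, trial) {
    if (trials == "first") x[trial == 1][1] else mean(x)
  }
  ids <- tibble::tibble(subject_id = cohort$subjects$subject_id)

  morpho <- cohort$subjects |>
    dplyr::transmute(
      .data$subject_id,
      growth = percent_change(.data$length_cm_t2, .data$length_cm_t1)
    )
  vent <- dplyr::left_join(
    cohort$ventilation,
    dplyr::select(
      cohort$subjects, "subject_id", "weight_g_t1"
    ),
    by = "subject_id"
  ) |>
    dplyr::transmute(
      .data$subject_id,
      basal_metabolism = basal_per_gram(
        .data$ventilation_basal_bpm, .data$weight_g_t1
      ),
      stress_metabolism = if (stress == "raw") {
        .data$ventilation_stress_bpm
      } else {
        percent_change(
          .data$ventilation_stress_bpm, .data$ventilation_basal_bpm
        )
      }
    )
  open <- cohort$open_field |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      activity = agg(.data$distance_cm, .data$trial),
      thigmotaxis = agg(
        zone_percentage(.data$time_outer_s, .data$time_total_s), .data$trial
      ),
      .groups = "drop"
    )
  scoto <- cohort$scototaxis |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      scototaxis = agg(
        zone_percentage(.data$time_dark_s, .data$time_total_s), .data$trial
      ),
      .groups = "drop"
    )
  socia <- cohort$sociability |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      sociability = agg(
        zone_percentage(
          .data$time_near_mirror_s, .data$time_total_s - .data$time_center_s
        ),
        .data$trial
      ),
      .groups = "drop"
    )
  lat <- cohort$lateralization |>
    dplyr::mutate(
      lateralization_indices(.data$time_cw_s, .data$time_ccw_s)
    ) |>
    dplyr::group_by(.data$subject_id, .data$test) |>
    dplyr::summarise(
      rel = agg(.data$relative, .data$trial),
      abs = agg(.data$absolute, .data$trial),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "test", values_from = c("rel", "abs")
    )
  for (col in c("rel_motor", "abs_motor", "rel_visual", "abs_visual")) {
    if (!col %in% names(lat)) lat[[col]] <- NA_real_
  }
  lat <- dplyr::rename(
    lat,
    motor_lat_rel = "rel_motor", motor_lat_abs = "abs_motor",
    visual_lat_rel = "rel_visual", visual_lat_abs = "abs_visual"
  )
  phases <- maze_phase_results(cohort) |>
    dplyr::select("subject_id", "phase", "days_to_criterion") |>
    tidyr::pivot_wider(
      names_from = "phase", values_from = "days_to_criterion"
    )
  for (ph in c("learning", "reversal", "memory")) {
    if (!ph %in% names(phases)) phases[[ph]] <- NA_integer_
  }
  maze <- phases |>
    dplyr::transmute(
      .data$subject_id,
      spatial_learning = as.numeric(.data$learning),
      flexibility = if (flexibility == "raw") {
        as.numeric(.data$reversal)
      } else {
        phase_index(.data$reversal, .data$learning)
      },
      memory = phase_index(.data$memory, .data$reversal)
    )

  out <- ids |>
    dplyr::left_join(morpho, by = "subject_id") |>
    dplyr::left_join(vent, by = "subject_id") |>
    dplyr::left_join(open, by = "subject_id") |>
    dplyr::left_join(scoto, by = "subject_id") |>
    dplyr::left_join(socia, by = "subject_id") |>
    dplyr::left_join(lat, by = "subject_id") |>
    dplyr::left_join(maze, by = "subject_id") |>
    dplyr::select(dplyr::all_of(c("subject_id", trait_names())))
  attr(out, "aggregation") <- list(
    trials = trials, stress = stress, flexibility = flexibility
  )
  out
}

#' Write or read a trait table with its aggregation sidecar
#'
#' @param table A trait table from [build_trait_table()].
#' @param path Path of the TSV file; a `.json` sidecar with the aggregation
#'   rule is written next to it.
#' @return `write_trait_table()` returns `path` invisibly;
#'   `read_trait_table()` the tibble with the sidecar re-attached.
#' @export
write_trait_table <- function(table, path) {
  readr::write_tsv(table, path)
  agg <- attr(table, "aggregation")
  if (!is.null(agg)) {
    jsonlite::write_json(agg, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "aggregation") <- jsonlite::read_json(
      sidecar,
      simplifyVector = TRUE
    )
  }
  out
}
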