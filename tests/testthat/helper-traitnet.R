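# Shared fixtures, all built in code.

trait_names_all <- function() {
  c(
    "growth", "basal_metabolism", "stress_metabolism", "activity",
    "thigmotaxis", "scototaxis", "sociability",
    "motor_lat_rel", "motor_lat_abs", "visual_lat_rel", "visual_lat_abs",
    "spatial_learning", "flexibility", "memory"
  )
}

nodes_12 <- function() {
  setdiff(trait_names_all(), c("motor_lat_rel", "visual_lat_rel"))
}

# latent correlation with planted partial-correlation edges: build the
# precision matrix with -pc on the chosen pairs and invert
planted_latent_corr <- function(pairs, pc = 0.45) {
  tn <- trait_names_all()
  omega <- diag(length(tn))
  dimnames(omega) <- list(tn, tn)
  for (p in pairs) {
    omega[p[1], p[2]] <- omega[p[2], p[1]] <- -pc
  }
  stats::cov2cor(solve(omega))
}

# pairs whose conditional dependence is induced by the scoring formulas
# themselves (shared day counts between the maze indices, shared raw times
# between the relative and absolute lateralization of one test); these are
# real associations of the scored traits, not method false positives
structurally_coupled_pairs <- function() {
  list(
    c("spatial_learning", "flexibility"),
    c("flexibility", "memory"),
    c("spatial_learning", "memory"),
    c("motor_lat_rel", "motor_lat_abs"),
    c("visual_lat_rel", "visual_lat_abs")
  )
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# small deterministic cohort for unit tests
small_cohort <- function(seed = 1, n = 12, ...) {
  generate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
}

# one-subject raw cohort built by hand, with known raw values
handmade_cohort <- function() {
  ids <- c("A", "B", "C", "D")
  maze <- tidyr::expand_grid(
    subject_id = ids,
    phase = c("learning", "reversal", "memory"),
    day = 1:2, trial = 1:6
  )
  maze$correct <- 1L # every phase solved on day 2 (counts 6 + 6)
  structure(
    list(
      subjects = tibble::tibble(
        subject_id = ids,
        length_cm_t1 = c(5, 5, 4, 5), weight_g_t1 = c(2, 2, 1.6, 2),
        length_cm_t2 = c(5.5, 5, 4.4, 6), weight_g_t2 = c(2.4, 2.1, 1.9, 2.6)
      ),
      ventilation = tibble::tibble(
        subject_id = ids,
        ventilation_stress_bpm = c(300, 200, 320, 172),
        ventilation_basal_bpm = c(150, 200, 160, 172)
      ),
      open_field = tidyr::expand_grid(subject_id = ids, trial = 1:2) |>
        dplyr::mutate(
          distance_cm = c(1000, 2000, 1500, 1500, 800, 1200, 2000, 2000),
          time_outer_s = c(1080, 1440, 900, 900, 1800, 0, 600, 1200),
          time_total_s = 1800
        ),
      scototaxis = tidyr::expand_grid(subject_id = ids, trial = 1:2) |>
        dplyr::mutate(
          time_dark_s = c(1200, 1800, 900, 900, 1700, 1750, 1000, 1100),
          time_total_s = 1800
        ),
      sociability = tidyr::expand_grid(subject_id = ids, trial = 1:2) |>
        dplyr::mutate(
          time_near_mirror_s = c(300, 600, 600, 600, 200, 300, 900, 800),
          time_center_s = c(600, 600, 600, 600, 800, 900, 0, 200),
          time_total_s = 1800
        ),
      lateralization = tidyr::expand_grid(
        subject_id = ids, test = c("motor", "visual"), trial = 1:2
      ) |>
        dplyr::mutate(
          time_cw_s = c(
            300, 100, 400, 400, 200, 200, 0, 400,
            600, 500, 100, 300, 500, 450, 350, 300
          ),
          time_ccw_s = c(
            100, 300, 400, 400, 200, 200, 400, 0,
            200, 250, 300, 100, 500, 450, 350, 300
          ),
          time_center_s = 200, time_freeze_s = 100
        ),
      maze = maze
    ),
    config = cohort_config(n_subjects = 4, seed = 1),
    class = "raw_cohort"
  )
}
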