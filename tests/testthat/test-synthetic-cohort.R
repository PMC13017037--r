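test_that("config validation rejects bad inputs with informative messages", {
  bad <- diag(14)
  bad[1, 2] <- bad[2, 1] <- 1.5 # breaks PSD
  expect_error(cohort_config(latent_corr = bad), "eigenvalue")
  expect_error(cohort_config(trait_means = 1:3), "length 14")
  expect_error(cohort_config(n_subjects = 2), "n_subjects")
  expect_error(cohort_config(missing_rate = 1.2), "missing_rate")
  asym <- diag(14)
  asym[1, 2] <- 0.3
  expect_error(cohort_config(latent_corr = asym), "symmetric")
})

test_that("same config and seed give identical cohorts, different seeds differ", {
  cfg <- cohort_config(n_subjects = 10, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (nm in names(a)) expect_identical(a[[nm]], b[[nm]])
  c <- generate_cohort(cohort_config(n_subjects = 10, seed = 43))
  expect_false(identical(a$subjects, c$subjects))
})

test_that("raw records respect duration and maze invariants", {
  co <- small_cohort(seed = 7, n = 20)
  expect_true(all(co$open_field$time_outer_s >= 0))
  expect_true(all(co$open_field$time_outer_s <= co$open_field$time_total_s))
  expect_true(all(co$scototaxis$time_dark_s <= co$scototaxis$time_total_s))
  with(co$sociability, {
    expect_true(all(time_near_mirror_s + time_center_s <= time_total_s))
  })
  with(co$lateralization, {
    expect_true(all(time_cw_s >= 0 & time_ccw_s >= 0))
    expect_true(all(
      abs(time_cw_s + time_ccw_s + time_center_s + time_freeze_s - 1800) <
        1e-9
    ))
  })
  # exactly 6 trials per day, all 0/1
  days <- dplyr::count(co$maze, subject_id, phase, day)
  expect_true(all(days$n == 6))
  expect_true(all(co$maze$correct %in% 0:1))
})

test_that("maze phases are truncated on the first criterion day", {
  co <- small_cohort(seed = 3, n = 24)
  daily <- co$maze |>
    dplyr::group_by(subject_id, phase, day) |>
    dplyr::summarise(n_correct = sum(correct), .groups = "drop")
  max_days <- attr(co, "config")$max_days
  by_phase <- split(daily, interaction(daily$subject_id, daily$phase,
    drop = TRUE
  ))
  for (d in by_phase) {
    d <- d[order(d$day), ]
    dc <- days_to_criterion(d$n_correct)
    if (!is.na(dc)) {
      expect_identical(max(d$day), dc) # no day recorded after criterion
    } else {
      expect_identical(max(d$day), max_days)
    }
  }
})

test_that("identity latent correlation yields near-null trait correlations", {
  cfg <- cohort_config(
    n_subjects = 500, trial_icc = 1, missing_rate = 0, seed = 5
  )
  tt <- build_trait_table(generate_cohort(cfg))
  cm <- correlation_matrix(tt)
  off <- abs(cm$rho[upper.tri(cm$rho)])
  expect_lt(mean(off), 0.1)
})

test_that("a planted latent correlation survives the monotone observable maps", {
  sig <- diag(14)
  sig[4, 8] <- sig[8, 4] <- 0.8 # activity <-> motor lateralization (rel)
  cfg <- cohort_config(
    n_subjects = 500, latent_corr = sig, trial_icc = 1,
    missing_rate = 0, seed = 6
  )
  tt <- build_trait_table(generate_cohort(cfg))
  cm <- correlation_matrix(tt)
  expect_gt(cm$rho["activity", "motor_lat_rel"], 0.5)
  # every pair not planted and not structurally coupled stays near zero
  excluded <- vapply(
    c(structurally_coupled_pairs(), list(c("activity", "motor_lat_rel"))),
    function(p) edge_key(p[1], p[2]), character(1)
  )
  idx <- which(upper.tri(cm$rho), arr.ind = TRUE)
  keys <- edge_key(cm$nodes[idx[, 1]], cm$nodes[idx[, 2]])
  expect_lt(max(abs(cm$rho[upper.tri(cm$rho)][!keys %in% excluded])), 0.15)
})

test_that("deterministic continuous maps recover latent ranks at large n", {
  # growth, basal and stress metabolism are deterministic monotone maps of
  # their latents; their pairwise Spearman correlations converge to the
  # planted values
  sig <- diag(14)
  sig[1, 2] <- sig[2, 1] <- 0.6
  sig[2, 3] <- sig[3, 2] <- -0.4
  cfg <- cohort_config(
    n_subjects = 5000, latent_corr = sig, trial_icc = 1,
    missing_rate = 0, seed = 8
  )
  tt <- build_trait_table(generate_cohort(cfg))
  r12 <- spearman(tt$growth, tt$basal_metabolism)$rho
  r23 <- spearman(tt$basal_metabolism, tt$stress_metabolism)$rho
  # Spearman of a bivariate normal is 6/pi asin(rho/2), slightly below rho
  expect_equal(r12, 6 / pi * asin(0.6 / 2), tolerance = 0.05 / 0.58)
  expect_equal(r23, 6 / pi * asin(-0.4 / 2), tolerance = 0.05 / 0.39)
})

test_that("missingness injection is block-wise with the right expectation", {
  co <- small_cohort(seed = 2, n = 24, missing_rate = 0)
  expect_identical(inject_missingness(co, 0), co)

  # rate 1: all eligible blocks gone, morphometrics intact
  full <- inject_missingness(co, 1, seed = 1)
  expect_identical(full$subjects, co$subjects)
  expect_false("visual" %in% full$lateralization$test)
  expect_identical(sort(unique(full$maze$phase)), "learning")

  # expectation: mean missing-cell fraction of the 24 x 14 table ~ 6/336
  fr <- vapply(1:150, function(s) {
    tt <- build_trait_table(
      generate_cohort(cohort_config(n_subjects = 24, seed = s))
    )
    mean(is.na(tt[trait_names_all()]))
  }, numeric(1))
  expect_equal(mean(fr), 6 / 336, tolerance = 0.15)

  expect_error(inject_missingness(co, -0.1), "rate")
  expect_error(inject_missingness(co, 1.1), "rate")
})

test_that("missingness mimics dropout: whole later-assay blocks per subject", {
  co <- inject_missingness(small_cohort(seed = 9, n = 24, missing_rate = 0),
    rate = 0.15, seed = 4
  )
  tt <- build_trait_table(co)
  miss <- attr(co, "missingness")
  expect_gt(length(c(miss$withdrawn_stage1, miss$withdrawn_stage2)), 0)
  for (id in miss$withdrawn_stage1) {
    row <- tt[tt$subject_id == id, ]
    expect_true(all(is.na(
      row[c("visual_lat_rel", "visual_lat_abs", "flexibility", "memory")]
    )))
    expect_false(anyNA(row[c("growth", "thigmotaxis", "spatial_learning")]))
  }
  for (id in miss$withdrawn_stage2) {
    row <- tt[tt$subject_id == id, ]
    expect_true(is.na(row$memory))
    expect_false(anyNA(row[c("visual_lat_abs", "flexibility")]))
  }
})

test_that("cohorts round-trip exactly through the delimited-text writer", {
  co <- small_cohort(seed = 13, n = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  for (nm in names(co)) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(co[[nm]]),
      tolerance = 1e-12
    )
  }
  # numeric values survive exactly (round-trippable text representation)
  expect_identical(back$subjects$length_cm_t1, co$subjects$length_cm_t1)
  cfg <- attr(back, "config")
  expect_identical(cfg$n_subjects, attr(co, "config")$n_subjects)
  expect_equal(cfg$latent_corr, attr(co, "config")$latent_corr)
})
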