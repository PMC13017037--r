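test_that("index formulas match hand computations", {
  expect_equal(percent_change(5.5, 5), 10)
  expect_equal(percent_change(300, 150), 100)
  expect_equal(percent_change(7.3, 7.3), 0)
  expect_error(percent_change(1, 0), "baseline")

  expect_equal(zone_percentage(1200, 1800), 200 / 3)
  expect_equal(zone_percentage(0, 1800), 0)
  expect_equal(zone_percentage(1800, 1800), 100)
  expect_equal(zone_percentage(300, 1800 - 600), 25) # sociability form
  expect_warning(out <- zone_percentage(10, 0), "denominator")
  expect_true(is.na(out))
  expect_error(zone_percentage(20, 10), "time_in")

  expect_equal(basal_per_gram(172, 2), 86)
  expect_equal(basal_per_gram(0, 2), 0)
  expect_equal(basal_per_gram(160, 1.6), 100)
  expect_error(basal_per_gram(100, 0), "weight")

  expect_equal(phase_index(8, 4), -1)
  expect_equal(phase_index(5, 5), 0)
  expect_equal(phase_index(2, 4), 0.5)
  expect_error(phase_index(3, 0), "baseline")
})

test_that("lateralization indices sign, bound and degenerate behavior", {
  li <- lateralization_indices(300, 100)
  expect_equal(li$relative, 50)
  expect_equal(li$absolute, 50)
  expect_equal(lateralization_indices(250, 250)$relative, 0)
  li2 <- lateralization_indices(0, 400)
  expect_equal(li2$relative, -100)
  expect_equal(li2$absolute, 100)
  expect_warning(li3 <- lateralization_indices(0, 0), "zero")
  expect_true(is.na(li3$relative))
  expect_error(lateralization_indices(-1, 5), "non-negative")
  # absolute always |relative| at the trial level
  set.seed(1)
  cw <- runif(50, 0, 900)
  ccw <- runif(50, 0, 900)
  li4 <- lateralization_indices(cw, ccw)
  expect_equal(li4$absolute, abs(li4$relative))
  expect_true(all(li4$relative >= -100 & li4$relative <= 100))
})

test_that("days_to_criterion scans overlapping two-day windows", {
  expect_identical(days_to_criterion(c(3, 4, 5, 6)), 4L)
  expect_identical(days_to_criterion(c(6, 4)), 2L) # fastest possible
  expect_identical(days_to_criterion(c(5, 4, 5, 4, 5)), NA_integer_)
  expect_identical(days_to_criterion(c(5, 5)), 2L)
  expect_identical(days_to_criterion(6), NA_integer_)
  expect_identical(days_to_criterion(integer(0)), NA_integer_)
  expect_error(days_to_criterion(c(3, 7)), "counts")

  # invariant to appending days after the criterion day
  set.seed(4)
  for (i in 1:50) {
    base <- sample(0:6, sample(2:10, 1), replace = TRUE)
    d <- days_to_criterion(base)
    if (!is.na(d)) {
      extended <- c(base[seq_len(d)], sample(0:6, 3, replace = TRUE))
      expect_identical(days_to_criterion(extended), d)
    }
  }
})

test_that("thigmotaxis chance level reproduces the 40% arena geometry", {
  expect_equal(chance_level("square_band", side = 40, band = 4.5), 39.9375)
  expect_equal(round(chance_level("square_band", side = 40, band = 4.5)), 40)
  expect_equal(chance_level("square_band", side = 40, band = 0), 0)
  expect_equal(chance_level("square_band", side = 40, band = 20), 100)
  expect_equal(chance_level("half_split"), 50)
  expect_error(chance_level("square_band", side = 40, band = 21), "band")
})

test_that("trait table matches hand-scored values on a handmade cohort", {
  tt <- build_trait_table(handmade_cohort())
  expect_identical(nrow(tt), 4L)
  a <- tt[tt$subject_id == "A", ]
  expect_equal(a$growth, 10)
  expect_equal(a$basal_metabolism, 75)
  expect_equal(a$stress_metabolism, 100)
  expect_equal(a$activity, 1500)
  expect_equal(a$thigmotaxis, 70) # mean of 60% and 80%
  expect_equal(a$sociability, 37.5) # mean of 25 and 50
  expect_equal(a$motor_lat_rel, 0) # +50 and -50 cancel
  expect_equal(a$motor_lat_abs, 50) # strength survives averaging
  expect_equal(a$spatial_learning, 2)
  expect_equal(a$flexibility, 0)
  expect_equal(a$memory, 0)
  b <- tt[tt$subject_id == "B", ]
  expect_equal(b$visual_lat_rel, 0)
  expect_equal(b$visual_lat_abs, 100)
})

test_that("first-trial aggregation and raw control variables", {
  co <- handmade_cohort()
  tt1 <- build_trait_table(co, trials = "first")
  expect_equal(tt1$thigmotaxis[tt1$subject_id == "A"], 60)
  expect_equal(tt1$motor_lat_rel[tt1$subject_id == "A"], 50)
  # under first-trial aggregation absolute equals |relative| exactly
  expect_equal(tt1$motor_lat_abs, abs(tt1$motor_lat_rel))
  expect_equal(tt1$visual_lat_abs, abs(tt1$visual_lat_rel))

  ttc <- build_trait_table(co, stress = "raw", flexibility = "raw")
  expect_equal(
    ttc$stress_metabolism,
    co$ventilation$ventilation_stress_bpm
  )
  expect_equal(ttc$flexibility, rep(2, 4)) # raw reversal days
})

test_that("missing assay blocks propagate to missing cells only", {
  co <- handmade_cohort()
  co$maze <- dplyr::filter(
    co$maze, !(subject_id == "B" & phase == "memory")
  )
  tt <- build_trait_table(co)
  b <- tt[tt$subject_id == "B", ]
  expect_true(is.na(b$memory))
  expect_false(anyNA(b[setdiff(trait_names_all(), "memory")]))
})

test_that("trait table is order-independent and idempotent in subjects", {
  co <- small_cohort(seed = 21, n = 10)
  tt <- build_trait_table(co)
  shuffled <- co
  perm <- c(4, 1, 3, 2, 8, 5, 10, 9, 6, 7)
  shuffled$subjects <- co$subjects[perm, ]
  for (nm in setdiff(names(co), "subjects")) {
    shuffled[[nm]] <- dplyr::arrange(co[[nm]], dplyr::desc(subject_id))
  }
  tt2 <- build_trait_table(shuffled)
  tt2 <- tt2[match(tt$subject_id, tt2$subject_id), ]
  expect_equal(as.data.frame(tt2), as.data.frame(tt), ignore_attr = TRUE)
  expect_equal(
    as.data.frame(build_trait_table(co)), as.data.frame(tt),
    ignore_attr = TRUE
  )
})

test_that("trait tables round-trip with their aggregation sidecar", {
  tt <- build_trait_table(handmade_cohort(), trials = "first")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trait_table(tt, path)
  back <- read_trait_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tt), ignore_attr = TRUE)
  expect_identical(attr(back, "aggregation")$trials, "first")
})
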