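# Synthetic-study generator: reproducibility, calibration and study design.

test_that("study designs validate their cohort structure", {
  d <- study_design()
  expect_true("NOC" %in% d$cells$group)
  expect_equal(d$cells$arm[d$cells$group == "NOC"], "none")
  expect_equal(nrow(d$cells), 7)  # 3 groups x 2 arms + NOC
  expect_error(study_design(n_sheep_per_cell = 0), "n_sheep_per_cell")
})

test_that("presets validate their invariants", {
  p <- default_presets()[["MSC-endpoint"]]
  expect_error(cohort_preset("bad", p$loop_params, 1.5, 0.01,
                             p$histo_criterion_means, 0.2,
                             gag_ug_mg = p$gag_ug_mg, hyp_ug_mg = p$hyp_ug_mg,
                             expr_mult = p$expr_mult),
               "dhi_ratio_mean")
  bad_means <- p$histo_criterion_means; bad_means[1] <- 9
  expect_error(cohort_preset("bad", p$loop_params, 0.9, 0.01,
                             bad_means, 0.2,
                             gag_ug_mg = p$gag_ug_mg, hyp_ug_mg = p$hyp_ug_mg,
                             expr_mult = p$expr_mult),
               "scheme range")
  expect_error(cohort_preset("bad", p$loop_params, 0.9, -0.1,
                             p$histo_criterion_means, 0.2,
                             gag_ug_mg = p$gag_ug_mg, hyp_ug_mg = p$hyp_ug_mg,
                             expr_mult = p$expr_mult),
               "dispersions")
})

test_that("identical seed and preset give bit-identical tables", {
  design <- small_design()
  preset <- default_presets()[["PBS-endpoint"]]
  expect_identical(generate_histo_profiles(preset, design, 9),
                   generate_histo_profiles(preset, design, 9))
  expect_identical(generate_landmarks(preset, design, 9),
                   generate_landmarks(preset, design, 9))
  p1 <- generate_plate_data(preset, design, 9)
  p2 <- generate_plate_data(preset, design, 9)
  expect_identical(p1$ct_table, p2$ct_table)
  expect_identical(p1$assay_samples, p2$assay_samples)
  # a different seed changes the draws
  expect_false(identical(generate_landmarks(preset, design, 9),
                         generate_landmarks(preset, design, 10)))
})

test_that("generators leave the caller's RNG state untouched", {
  design <- small_design()
  set.seed(99)
  before <- .Random.seed
  invisible(generate_histo_profiles(default_presets()[["NOC"]], design, 3))
  expect_identical(.Random.seed, before)
})

test_that("zero-dispersion histo cohorts equal the criterion means exactly", {
  design <- small_design()
  preset <- zero_noise_preset(default_presets()[["MSC-endpoint"]])
  tab <- histo_cumulative_table(generate_histo_profiles(preset, design, 1))
  expect_equal(tab$cumulative,
               rep(sum(preset$histo_criterion_means), nrow(tab)))
  expect_equal(tab$mean_disagreement, rep(0, nrow(tab)))
})

test_that("preset expectations match the cohort summaries they emulate", {
  # large-sample check of the calibration: the generated cumulative-score
  # expectation equals the documented cohort means (2, 22, 19, 4) and the
  # percent-DHI expectation the documented height ratios
  design <- study_design(n_sheep_per_cell = 60)
  presets <- default_presets()
  expected <- c("NOC" = 2, "degenerate-baseline" = 22,
                "PBS-endpoint" = 19, "MSC-endpoint" = 4)
  for (nm in names(expected)) {
    tab <- histo_cumulative_table(
      generate_histo_profiles(presets[[nm]], design, seed = 13))
    se <- sd(tab$cumulative) / sqrt(nrow(tab))
    expect_lt(abs(mean(tab$cumulative) - expected[[nm]]),
              3 * max(se, 0.02))
    expect_equal(sum(presets[[nm]]$histo_criterion_means), expected[[nm]])
  }
})

test_that("loop ground truth travels with generated records", {
  design <- study_design(n_sheep_per_cell = 2)
  recs <- generate_loading_records(default_presets()[["NOC"]], design, 21)
  expect_length(recs, 6)  # 2 sheep x 3 modes
  ar <- recs[["1/axial_rotation"]]
  expect_false(ar$truth$nz_present)  # no region of low stiffness
  fe <- recs[["1/flexion_extension"]]
  expect_true(fe$truth$nz_present)
  expect_gt(fe$truth$nz_width, 0)
})
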