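# Cumulative histopathology scoring and observer reconciliation.

test_that("cumulative score is the sum of the six criteria", {
  expect_equal(cumulative_score(histo_profile(rep(0, 6))), 0)
  expect_equal(cumulative_score(histo_profile(rep(5, 6))), 30)
  expect_equal(cumulative_score(histo_profile(c(4, 5, 3, 4, 3, 3))), 22)
})

test_that("out-of-range and incomplete profiles are rejected", {
  expect_error(cumulative_score(histo_profile(c(6, 0, 0, 0, 0, 0))),
               "out of range")
  expect_error(cumulative_score(histo_profile(c(-1, 0, 0, 0, 0, 0))),
               "out of range")
  p <- histo_profile(rep(1, 6))[-2]
  expect_error(cumulative_score(p), "missing criterion")
  expect_error(scoring_scheme(stats::setNames(rep(5, 6), letters[1:6])),
               "criteria")
})

test_that("reconciliation averages observers with half-up rounding", {
  sheet <- tibble::tibble(
    disc = "d1", observer = rep(1:2, each = 6),
    criterion = rep(HISTO_CRITERIA, 2),
    score = c(2, 3, 1, 0, 4, 5, 3, 3, 1, 0, 4, 5))
  cons <- reconcile_observers(sheet)
  expect_equal(cons$score[1], 3)          # mean 2.5 rounds up
  expect_equal(cons$disagreement[1], 1)
  expect_equal(cons$score[-1], c(3, 1, 0, 4, 5))
  # identical observers reproduce themselves
  same <- sheet; same$score <- rep(c(2, 3, 1, 0, 4, 5), 2)
  expect_equal(reconcile_observers(same)$score, c(2, 3, 1, 0, 4, 5))
  expect_equal(reconcile_observers(same)$disagreement, rep(0, 6))
})

test_that("reconciliation is idempotent and observer-order invariant", {
  sheet <- tibble::tibble(
    disc = "d1", observer = rep(1:2, each = 6),
    criterion = rep(HISTO_CRITERIA, 2),
    score = c(2, 3, 1, 0, 4, 5, 3, 4, 0, 0, 4, 4))
  cons <- reconcile_observers(sheet)
  swapped <- sheet; swapped$observer <- rep(2:1, each = 6)
  expect_equal(reconcile_observers(swapped)$score, cons$score)
  again <- tibble::tibble(disc = "d1", observer = 1,
                          criterion = cons$criterion, score = cons$score)
  expect_equal(reconcile_observers(again)$score, cons$score)
  # conflicting disc ids are rejected
  bad <- sheet; bad$disc[1] <- "d2"
  expect_error(reconcile_observers(bad), "conflicting disc")
})

test_that("cohort summaries give box-plot statistics", {
  s <- cohort_scores(rep(4, 6))
  expect_equal(s$mean, 4); expect_equal(s$sd, 0)
  expect_equal(c(s$q25, s$q75), c(4, 4))
  s2 <- cohort_scores(1:6)
  expect_equal(s2$median, 3.5)
  expect_equal(s2$q25, unname(quantile(1:6, 0.25)))
  expect_equal(s2$q75, unname(quantile(1:6, 0.75)))
  expect_error(cohort_scores(3), "at least 2")
})

test_that("cumulative score is monotone in every criterion", {
  base <- histo_profile(c(2, 3, 1, 0, 4, 2))
  s0 <- cumulative_score(base)
  for (k in seq_along(base)) {
    up <- base; up[k] <- up[k] + 1
    expect_gt(cumulative_score(up), s0)
  }
})

test_that("synthetic two-observer cohorts disagree by at most one step", {
  design <- small_design()
  prof <- generate_histo_profiles(default_presets()[["PBS-endpoint"]],
                                  design, seed = 3)
  tab <- histo_cumulative_table(prof)
  expect_true(all(tab$mean_disagreement <= 1))
  wide <- split(prof$score, prof$observer)
  expect_true(all(abs(wide[[1]] - wide[[2]]) <= 1))
})

test_that("cohort mean cumulative score tracks the preset expectation", {
  design <- small_design()
  preset <- default_presets()[["PBS-endpoint"]]
  tab <- histo_cumulative_table(generate_histo_profiles(preset, design,
                                                        seed = 3))
  expected <- sum(preset$histo_criterion_means)
  se <- sqrt(6) * preset$histo_criterion_sd / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$cumulative) - expected), 2 * se)
})
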