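# Torque-angle estimators: final-cycle extraction, ROM, polynomial fits,
# gradient-threshold neutral zone and initial stiffness.

noiseless <- function(k_nz, k_el, w, off = 0)
  hysteresis_params(k_nz, k_el, w, hysteresis_offset = off, noise_sd = 0)

test_that("the final full cycle is extracted", {
  rec <- simulate_loop(noiseless(0.02, 3, 3), seed = 1)
  fin <- extract_final_cycle(rec)
  expect_true(all(fin$samples$cycle == 10))
  expect_identical(nrow(fin$samples),
                   sum(rec$samples$cycle == 10))
  # a single-cycle record is returned unchanged
  one <- rec
  one$samples <- rec$samples[rec$samples$cycle == 1, ]
  expect_identical(extract_final_cycle(one)$samples, one$samples)
  # a record cut off mid-sweep has no complete cycle
  frag <- rec
  quarter <- rec$samples$cycle == 1 &
    rec$samples$time_s < min(rec$samples$time_s[rec$samples$cycle == 2]) / 4
  frag$samples <- rec$samples[quarter, ]
  expect_error(extract_final_cycle(frag), "incomplete record")
})

test_that("ROM is the deflection between the torque extremes", {
  rec <- simulate_loop(noiseless(1, 1, 0), seed = 1)  # torque = angle
  expect_equal(compute_rom(extract_final_cycle(rec)), 10, tolerance = 1e-9)
  # noiseless dual-stiffness loop: within one sample spacing of the truth
  rec2 <- simulate_loop(noiseless(0.02, 3, 3), seed = 1)
  expect_lt(abs(compute_rom(extract_final_cycle(rec2)) - rec2$truth$rom), 0.25)
  # monotone torque without sign change is rejected
  smp <- poly_direction_samples(c(2, 1), c(0, 5))
  expect_error(compute_rom(smp), "sign")
})

test_that("degree-7 polynomials are recovered exactly", {
  coefs <- c(0.1, 0.05, 0, 2e-3, 0, -1e-4, 0, 5e-6)
  smp <- poly_direction_samples(coefs, c(-8, 8))
  fit <- fit_direction(smp)
  expect_lt(fit$rms, 1e-8)
  th <- seq(-7.9, 7.9, length.out = 50)
  truth <- drop(outer(th, 0:7, "^") %*% coefs)
  expect_equal(predict_torque(fit, th), truth, tolerance = 1e-8)
})

test_that("linear data yield a constant fitted gradient", {
  smp <- poly_direction_samples(c(0, 2), c(-5, 5))
  fit <- fit_direction(smp)
  th <- seq(-4.9, 4.9, length.out = 20)
  expect_equal(predict_gradient(fit, th), rep(2, 20), tolerance = 1e-8)
  expect_equal(stiffness(fit), 2, tolerance = 1e-8)
})

test_that("fits reject short or rank-deficient directions", {
  smp <- poly_direction_samples(c(0, 1), c(-5, 5), n = 8)
  expect_error(fit_direction(smp), "at least")
  rep_smp <- poly_direction_samples(c(0, 1), c(-5, 5), n = 40)
  rep_smp$angle_deg <- rep(seq(-5, 5, length.out = 5), each = 8)
  expect_error(fit_direction(rep_smp), "distinct angles")
  fit <- fit_direction(poly_direction_samples(c(0, 1), c(-5, 5)))
  expect_error(predict_torque(fit, 6), "outside fit domain")
})

test_that("fit residuals stay at the noise level", {
  p <- hysteresis_params(0.02, 3, 3, noise_sd = 0.05)
  rms <- vapply(1:10, function(s) {
    smp <- extract_final_cycle(simulate_loop(p, seed = s))$samples
    fit_direction(smp[smp$direction == "loading_positive", ])$rms
  }, numeric(1))
  expect_true(all(rms <= 2 * 0.05))
})

test_that("neutral zone is absent when the gradient never drops below threshold", {
  smp <- poly_direction_samples(c(0, 0.2), c(-6, 6))
  f <- fit_direction(smp)
  nz <- neutral_zone(f, f)
  expect_false(nz$present)
  expect_equal(nz$width, 0)
})

test_that("a symmetric sub-threshold plateau of [-3, 3] gives NZ width 6", {
  rec <- simulate_loop(noiseless(0.01, 3, 3), seed = 1)
  res <- analyze_record(rec)
  expect_true(res$nz_present)
  expect_equal(res$nz_width_deg, 6, tolerance = 0.03)
  expect_equal(res$nz_range, c(-3, 3), tolerance = 0.03)
})

test_that("the common overlap of plateaus [-3,3] and [-1,5] is [-1,3]", {
  # direction curves built so the strict sub-0.05 gradient regions are
  # exactly (-3, 3) and (-1, 5): gradient g(th) = 0.001 + d*((th-c)/a)^4
  # crosses 0.05 at c +/- 3 when a = 3 / ((0.05-0.001)/d)^(1/4)
  quartic_dir <- function(centre, d = 2, dirlab) {
    a <- 3 / ((0.05 - 0.001) / d)^0.25
    # torque = 0.001*(th-c) + d*(th-c)^5/(5 a^4), zero crossing at th = c
    th <- seq(-7, 9, length.out = 400)
    u <- th - centre
    tq <- 0.001 * u + d * u^5 / (5 * a^4)
    fit_direction(tibble::tibble(time_s = seq_along(th) / 20, angle_deg = th,
                                 torque_Nm = tq, cycle = 1L, direction = dirlab))
  }
  f1 <- quartic_dir(0, dirlab = "loading_positive")
  f2 <- quartic_dir(2, dirlab = "loading_negative")
  nz <- neutral_zone(f1, f2)
  expect_true(nz$present)
  expect_equal(nz$range, c(-1, 3), tolerance = 0.03)
  expect_equal(nz$width, 4, tolerance = 0.05)
})

test_that("disjoint fit domains are rejected", {
  f1 <- fit_direction(poly_direction_samples(c(0, 1), c(-5, -1)))
  f2 <- fit_direction(poly_direction_samples(c(0, 1), c(1, 5)))
  expect_error(neutral_zone(f1, f2), "disjoint")
})

test_that("stiffness requires a zero-torque crossing and averages directions", {
  smp <- poly_direction_samples(c(3, 1), c(0.1, 5))  # torque >= 3 throughout
  expect_error(stiffness(fit_direction(smp)), "no neutral position")
  expect_equal(final_stiffness(1, 3), 2)
})

test_that("noiseless loops recover the analytic stiffness within 5%", {
  for (p in list(noiseless(0.02, 3, 3, off = 0.3),
                 noiseless(0.4, 2.5, 2, off = 0.3))) {   # incl. no-NZ mode
    res <- analyze_record(simulate_loop(p, seed = 2))
    truth <- loop_truth(p)
    expect_lt(abs(res$final_stiffness - truth$stiffness_final) /
                truth$stiffness_final, 0.05)
    expect_equal(res$final_stiffness,
                 (res$stiffness_pos + res$stiffness_neg) / 2)
  }
})

test_that("raising the threshold never shrinks the neutral zone", {
  rec <- simulate_loop(hysteresis_params(0.02, 3, 3, noise_sd = 0.05), seed = 5)
  smp <- extract_final_cycle(rec)$samples
  fp <- fit_direction(smp[smp$direction == "loading_positive", ])
  fn <- fit_direction(smp[smp$direction == "loading_negative", ])
  widths <- vapply(c(0.03, 0.05, 0.08, 0.12),
                   function(thr) neutral_zone(fp, fn, threshold = thr)$width,
                   numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("estimated NZ width grows with the generator half-width", {
  widths <- vapply(c(1, 2, 3, 4.5), function(w) {
    analyze_record(simulate_loop(noiseless(0.02, 3, w), seed = 3))$nz_width_deg
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
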