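# qPCR standard curves and total-RNA-normalised relative copy numbers.

test_that("perfect ten-fold dilutions give slope -1/log10(2) and 100% efficiency", {
  d <- 10^-(0:4)
  ct <- 15 - log10(d) / log10(2)
  curve <- fit_ct_curve(d, ct)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
  expect_error(fit_ct_curve(c(1, 0.1), c(15, 18.3)), "3 distinct")
  expect_error(fit_ct_curve(d, rev(ct)), "non-amplifying")
})

test_that("noisy dilution series recover the generating slope", {
  set.seed(4)
  d <- 10^-(0:4)
  err <- replicate(20, {
    ct <- 15 - log10(d) / log10(2) + rnorm(5, 0, 0.1)
    abs(fit_ct_curve(d, ct)$slope - (-1 / log10(2))) / (1 / log10(2))
  })
  expect_lt(median(err), 0.05)
})

test_that("one Ct below means exactly twofold copies at 100% efficiency", {
  d <- 10^-(0:4)
  curve <- list(MMP3 = fit_ct_curve(d, 15 - log10(d) / log10(2), "MMP3"))
  tab <- tibble::tibble(sample = c("a", "a", "a", "b", "b", "b"),
                        gene = "MMP3",
                        ct = c(rep(20, 3), rep(19, 3)), rna_ug = 1)
  rc <- relative_copies(tab, curve)
  expect_equal(rc$rel_copies[rc$sample == "b"] /
                 rc$rel_copies[rc$sample == "a"], 2, tolerance = 1e-9)
  # a Ct equal to a standard point returns that standard's copies
  tab2 <- tibble::tibble(sample = "s", gene = "MMP3",
                         ct = rep(15 - log10(1e-3) / log10(2), 3), rna_ug = 1)
  expect_equal(relative_copies(tab2, curve)$rel_copies, 1e-3, tolerance = 1e-9)
})

test_that("lower Ct never yields fewer copies", {
  d <- 10^-(0:4)
  curve <- list(g = fit_ct_curve(d, 15 - log10(d) / log10(2) +
                                   rnorm(5, 0, 0.05), "g"))
  cts <- seq(16, 28, by = 0.5)
  tab <- tibble::tibble(sample = paste0("s", seq_along(cts)), gene = "g",
                        ct = cts, rna_ug = 1)
  rc <- relative_copies(tab, curve)
  ord <- order(rc$mean_ct)
  expect_true(all(diff(rc$rel_copies[ord]) <= 0))
})

test_that("replicate outliers and missing curves are flagged", {
  d <- 10^-(0:4)
  curve <- list(MMP3 = fit_ct_curve(d, 15 - log10(d) / log10(2), "MMP3"))
  tab <- tibble::tibble(sample = "a", gene = "MMP3",
                        ct = c(19, 20, 20.5), rna_ug = 1)
  expect_true(relative_copies(tab, curve)$replicate_outlier)
  tab$gene <- "ACAN"
  expect_error(relative_copies(tab, curve), "missing standard curve")
})

test_that("zero-noise cohorts round-trip the preset fold changes exactly", {
  design <- small_design()
  presets <- default_presets()
  noc <- zero_noise_preset(presets[["NOC"]])
  pbs <- zero_noise_preset(presets[["PBS-endpoint"]])
  tabs <- lapply(list(NOC = noc, PBS = pbs), function(pr) {
    qp <- qpcr_table(generate_plate_data(pr, design, seed = 5))
    qp$group <- if (pr$name == "NOC") "NOC" else "EST"
    qp
  })
  folds <- fold_vs_noc(dplyr::bind_rows(tabs))
  for (g in c("MMP3", "MMP13", "ACAN", "TIMP1")) {
    got <- folds$fold_vs_noc[folds$gene == g]
    expect_equal(got, rep(unname(pbs$expr_mult[g]), length(got)),
                 tolerance = 1e-6)
  }
})

test_that("noisy cohorts recover fold changes within 10%", {
  design <- small_design()
  presets <- default_presets()
  tabs <- lapply(c("NOC", "PBS-endpoint"), function(nm) {
    qp <- qpcr_table(generate_plate_data(presets[[nm]], design, seed = 5))
    qp$group <- if (nm == "NOC") "NOC" else "EST"
    qp
  })
  folds <- fold_vs_noc(dplyr::bind_rows(tabs))
  mult <- presets[["PBS-endpoint"]]$expr_mult
  rel_err <- abs(folds$fold_vs_noc - mult[folds$gene]) / mult[folds$gene]
  expect_lt(median(rel_err), 0.10)
})
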