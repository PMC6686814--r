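# Cohort-level synthetic data generators. Each generator draws from its
# own named substream of the study seed, so tables are reproducible
# per-stage and bit-identical for identical (preset, design, seed).

truncnorm_pos <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep_len(mean, n))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  x
}

#' Generate paired radiograph landmark tables for one cohort
#'
#' For each sheep and disc level: a pre-surgery landmark set with known
#' vertebral-body and disc heights, and an endpoint set whose disc height
#' is the pre-surgery height scaled by a draw from
#' `Normal(dhi_ratio_mean, dhi_ratio_sd)` truncated to positive values.
#' Vertebral heights are unchanged. Every radiograph carries its own
#' similarity jitter (magnification, rotation, translation) that the disc
#' height index must cancel.
#'
#' @param preset A [cohort_preset()].
#' @param design A [study_design()].
#' @param seed Integer study seed.
#' @return Tibble (`sheep`, `disc_level`, `timepoint`, `point`, `x`, `y`)
#'   with attribute `truth`: tibble of the drawn height ratios per disc.
#' @export
generate_landmarks <- function(preset, design, seed) {
  stopifnot(inherits(preset, "cohort_preset"), inherits(design, "study_design"))
  old <- withr_seed(substream(seed, paste0("landmarks/", preset$name)))
  on.exit(restore_seed(old))
  n <- design$n_sheep_per_cell
  rows <- list(); truth <- list()
  for (level in design$disc_levels) {
    ratios <- truncnorm_pos(n, preset$dhi_ratio_mean, preset$dhi_ratio_sd)
    for (i in seq_len(n)) {
      base_dh <- 6; vb <- 30
      for (tp in c("pre_surgery", "endpoint")) {
        dh <- if (tp == "pre_surgery") base_dh else base_dh * ratios[i]
        lm <- synthetic_landmark_set(disc_height = dh, vb_height = vb)
        lm <- transform_landmarks(lm,
                                  scale = stats::runif(1, 0.85, 1.25),
                                  angle_deg = stats::runif(1, -12, 12),
                                  shift = stats::runif(2, -20, 20))
        lm$sheep <- i; lm$disc_level <- level; lm$timepoint <- tp
        rows[[length(rows) + 1]] <- lm
      }
      truth[[length(truth) + 1]] <-
        tibble::tibble(sheep = i, disc_level = level, ratio = ratios[i])
    }
  }
  out <- dplyr::bind_rows(rows)[, c("sheep", "disc_level", "timepoint",
                                    "point", "x", "y")]
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

# one ordinal criterion score with expectation exactly `mean`:
# floor(mean) + Bernoulli(fractional part), plus a symmetric integer
# jitter with discretised-normal weights truncated so it cannot cross the
# ordinal range (truncation is symmetric, so the expectation is
# untouched; realised dispersion is therefore bounded above by `sd`)
draw_criterion_score <- function(mean, max_score, sd) {
  base <- floor(mean)
  frac <- mean - base
  score <- base + (frac > 0 && stats::runif(1) < frac)
  jmax <- min(base, max_score - ceiling(mean))
  if (sd > 0 && jmax > 0) {
    k <- seq(-jmax, jmax)
    score <- score + sample(k, 1, prob = stats::dnorm(k, 0, sd))
  }
  score
}

#' Generate two-observer histopathology score sheets for one cohort
#'
#' Per disc (one histology disc per sheep) and criterion, observer 1 draws
#' a discrete range-respecting score whose expectation equals the preset's
#' criterion mean; observer 2 repeats observer 1's score but with
#' probability `observer_jitter_p` scores one ordinal step lower (clipped
#' at zero). This one-sided inter-observer jitter leaves the half-up
#' rounded-mean consensus equal to observer 1, so cohort expectations stay
#' tied to the criterion means.
#'
#' @inheritParams generate_landmarks
#' @return Tibble (`disc`, `sheep`, `observer`, `criterion`, `score`) with
#'   attribute `truth`: the preset's expected cumulative score (sum of
#'   criterion means).
#' @export
generate_histo_profiles <- function(preset, design, seed) {
  stopifnot(inherits(preset, "cohort_preset"), inherits(design, "study_design"))
  scheme <- preset$scheme
  m <- preset$histo_criterion_means
  if (any(m < 0) || any(m > scheme$max_scores))
    stop("criterion mean outside scheme range", call. = FALSE)
  old <- withr_seed(substream(seed, paste0("histo/", preset$name)))
  on.exit(restore_seed(old))
  n <- design$n_sheep_per_cell
  rows <- list()
  for (i in seq_len(n)) {
    o1 <- mapply(draw_criterion_score, m, scheme$max_scores,
                 MoreArgs = list(sd = preset$histo_criterion_sd))
    drop1 <- stats::runif(length(m)) < preset$observer_jitter_p
    o2 <- pmax(o1 - as.integer(drop1), 0)
    disc <- paste0(preset$name, "-L1L2-", i)
    rows[[length(rows) + 1]] <- tibble::tibble(
      disc = disc, sheep = i, observer = rep(1:2, each = length(m)),
      criterion = rep(HISTO_CRITERIA, 2), score = c(o1, o2))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- sum(m)
  out
}

#' Generate plate-reader and qPCR tables for one cohort
#'
#' Emits (i) a GAG standard series (known ug chondroitin sulfate vs
#' absorbance, linear with noise) plus triplicate sample absorbances
#' back-computed from the preset's zonal GAG contents and recorded wet
#' weights; (ii) the analogous hydroxyproline series and samples; (iii)
#' per-gene qPCR dilution series following `Ct = a + slope * log10(copies)`
#' plus triplicate sample Cts back-computed from the preset's expression
#' multipliers and total-RNA loadings.
#'
#' @inheritParams generate_landmarks
#' @param gag_standards,hyp_standards Requested standard amounts (ug),
#'   strictly increasing.
#' @return List: `gag_standards`, `hyp_standards` (`amount_ug`, `signal`),
#'   `assay_samples` (`analyte`, `sheep`, `zone`, `replicate`, `signal`,
#'   `wet_weight_mg`), `dilution_series` (`gene`, `copies`, `ct`),
#'   `ct_table` (`sample`, `sheep`, `zone`, `gene`, `ct`, `rna_ug`),
#'   `config` (digest bookkeeping and curve constants) and `truth` (zonal
#'   contents and normalised expression per sheep).
#' @export
generate_plate_data <- function(preset, design, seed,
                                gag_standards = c(0, 5, 10, 20, 30, 40),
                                hyp_standards = c(0, 2, 4, 6, 8, 10)) {
  stopifnot(inherits(preset, "cohort_preset"), inherits(design, "study_design"))
  if (any(diff(gag_standards) <= 0) || any(diff(hyp_standards) <= 0))
    stop("standard series must be strictly increasing", call. = FALSE)
  old <- withr_seed(substream(seed, paste0("plate/", preset$name)))
  on.exit(restore_seed(old))
  n <- design$n_sheep_per_cell
  zones <- design$zones
  noise0 <- preset$gag_cv == 0 && preset$hyp_cv == 0 && preset$expr_sdlog == 0
  sig_sd <- if (noise0) 0 else 0.004
  ct_sd <- if (noise0) 0 else 0.10
  config <- list(digest_volume_ml = 1, aliquot_volume_ml = 0.01,
                 gag_slope = 0.02, gag_intercept = 0.05,
                 hyp_slope = 0.08, hyp_intercept = 0.03,
                 ct_intercept = 15, ct_slope = -1 / log10(2),
                 base_copies = 0.01, signal_noise_sd = sig_sd,
                 ct_noise_sd = ct_sd)

  std <- function(amounts, slope, intercept)
    tibble::tibble(amount_ug = amounts,
                   signal = slope * amounts + intercept +
                     stats::rnorm(length(amounts), 0, sig_sd))
  gag_std <- std(gag_standards, config$gag_slope, config$gag_intercept)
  hyp_std <- std(hyp_standards, config$hyp_slope, config$hyp_intercept)

  frac <- config$aliquot_volume_ml / config$digest_volume_ml
  cells <- expand.grid(sheep = seq_len(n), zone = zones,
                       analyte = c("GAG", "hydroxyproline"),
                       stringsAsFactors = FALSE)
  mu <- ifelse(cells$analyte == "GAG",
               preset$gag_ug_mg[cells$zone], preset$hyp_ug_mg[cells$zone])
  cv <- ifelse(cells$analyte == "GAG", preset$gag_cv, preset$hyp_cv)
  slope <- ifelse(cells$analyte == "GAG", config$gag_slope, config$hyp_slope)
  icpt <- ifelse(cells$analyte == "GAG", config$gag_intercept,
                 config$hyp_intercept)
  ww <- if (noise0) rep(50, nrow(cells)) else truncnorm_pos(nrow(cells), 50, 5)
  content <- truncnorm_pos(nrow(cells), mu, cv * mu)
  amount <- content * ww * frac
  reps <- rep(seq_len(nrow(cells)), each = 3)
  samp <- tibble::tibble(
    analyte = cells$analyte[reps], sheep = cells$sheep[reps],
    zone = cells$zone[reps], replicate = rep(1:3, nrow(cells)),
    signal = slope[reps] * amount[reps] + icpt[reps] +
      stats::rnorm(length(reps), 0, sig_sd),
    wet_weight_mg = ww[reps])
  truth_tissue <- tibble::tibble(analyte = cells$analyte,
                                 sheep = cells$sheep, zone = cells$zone,
                                 ug_per_mg = content)

  dilutions <- 10^-(0:4)
  dil <- tibble::tibble(
    gene = rep(QPCR_GENES, each = length(dilutions)),
    copies = rep(dilutions, length(QPCR_GENES)))
  dil$ct <- config$ct_intercept + config$ct_slope * log10(dil$copies) +
    stats::rnorm(nrow(dil), 0, ct_sd)
  qcells <- expand.grid(sheep = seq_len(n), zone = zones, gene = QPCR_GENES,
                        stringsAsFactors = FALSE)
  expr <- config$base_copies * preset$expr_mult[qcells$gene] *
    exp(stats::rnorm(nrow(qcells), 0, preset$expr_sdlog))
  rna <- if (noise0) rep(1, nrow(qcells)) else
    stats::runif(nrow(qcells), 0.8, 1.2)
  qreps <- rep(seq_len(nrow(qcells)), each = 3)
  cts <- tibble::tibble(
    sample = paste0(preset$name, "-", qcells$zone, "-", qcells$sheep)[qreps],
    sheep = qcells$sheep[qreps], zone = qcells$zone[qreps],
    gene = qcells$gene[qreps],
    ct = config$ct_intercept + config$ct_slope * log10(expr * rna)[qreps] +
      stats::rnorm(length(qreps), 0, ct_sd),
    rna_ug = rna[qreps])
  truth_expr <- tibble::tibble(sheep = qcells$sheep, zone = qcells$zone,
                               gene = qcells$gene, norm_copies = expr)

  list(gag_standards = gag_std, hyp_standards = hyp_std,
       assay_samples = samp,
       dilution_series = dil,
       ct_table = cts,
       config = config,
       truth = list(tissue = truth_tissue, expression = truth_expr))
}

#' Generate biomechanics loading records for one cohort
#'
#' One cyclic torque-angle record per sheep and loading mode, from the
#' preset's per-mode hysteresis parameters.
#'
#' @inheritParams generate_landmarks
#' @return List of `loading_record` objects named `"sheep/mode"`.
#' @export
generate_loading_records <- function(preset, design, seed) {
  stopifnot(inherits(preset, "cohort_preset"), inherits(design, "study_design"))
  n <- design$n_sheep_per_cell
  out <- list()
  for (i in seq_len(n)) {
    for (mode in names(preset$loop_params)) {
      key <- paste0(i, "/", mode)
      out[[key]] <- simulate_loop(
        preset$loop_params[[mode]],
        seed = substream(seed, paste0("loop/", preset$name, "/", key)),
        specimen = paste0(preset$name, "-", i),
        loading_mode = mode)
    }
  }
  out
}
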