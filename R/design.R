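# Study design and cohort presets for the synthetic annular-lesion study.
#
# The emulated experiment: lumbar discs of merino wethers receive a
# controlled annular lesion; degeneration develops for 4 weeks (early/late
# acute groups, EA/LA) or 12 weeks (established group, EST); lesion discs
# are then injected with mesenchymal stem cells (MSC) or PBS carrier and
# recovered before sacrifice. Nonoperated controls (NOC) are uninjected.
# L1L2 discs feed histology, L3L4 gene expression, and L5L6 biomechanics
# and biochemistry; biochemical and expression assays are zonal (outer
# annulus AF1, inner annulus AF2, nucleus pulposus NP).

#' Define the cohort structure of a synthetic study
#'
#' @param groups Treatment groups; subset of `"EA"`, `"LA"`, `"EST"`.
#' @param arms Injection arms for the lesion groups; subset of `"PBS"`,
#'   `"MSC"`.
#' @param include_noc Include a nonoperated control cohort (arm `"none"`).
#' @param n_sheep_per_cell Sheep per (group, arm) cell (default 6, the
#'   per-analysis sample size of the emulated study).
#' @param disc_levels Operated disc levels.
#' @param zones Dissection zones for biochemical and expression assays.
#' @return A `study_design` with a `cells` tibble (`group`, `arm`) and the
#'   remaining fields as given.
#' @export
study_design <- function(groups = c("EA", "LA", "EST"),
                         arms = c("PBS", "MSC"),
                         include_noc = TRUE,
                         n_sheep_per_cell = 6,
                         disc_levels = c("L1L2", "L3L4", "L5L6"),
                         zones = c("AF1", "AF2", "NP")) {
  groups <- match.arg(groups, several.ok = TRUE)
  arms <- match.arg(arms, several.ok = TRUE)
  if (n_sheep_per_cell < 1) stop("n_sheep_per_cell must be >= 1", call. = FALSE)
  cells <- expand.grid(group = groups, arm = arms, stringsAsFactors = FALSE)
  if (include_noc) cells <- rbind(cells, data.frame(group = "NOC", arm = "none"))
  out <- list(cells = tibble::as_tibble(cells),
              n_sheep_per_cell = as.integer(n_sheep_per_cell),
              disc_levels = disc_levels, zones = zones)
  class(out) <- "study_design"
  out
}

#' Define a cohort preset
#'
#' A preset bundles the generating distributions of every input modality
#' for one cohort: hysteresis-loop parameters per loading mode, the
#' endpoint-to-pre-surgery disc-height ratio, per-criterion histopathology
#' score means and dispersion, zonal GAG and hydroxyproline contents, and
#' per-gene expression multipliers relative to nonoperated controls.
#'
#' @param name Preset label.
#' @param loop_params Named list of [hysteresis_params()] for
#'   `flexion_extension`, `lateral_bending`, `axial_rotation`.
#' @param dhi_ratio_mean,dhi_ratio_sd Endpoint disc height as a fraction of
#'   the pre-surgery value; mean must lie in (0, 1.2].
#' @param histo_criterion_means Named vector (see [HISTO_CRITERIA]) of
#'   per-criterion score means; each within its scheme range.
#' @param histo_criterion_sd Common per-criterion dispersion of the
#'   discretised score draws.
#' @param observer_jitter_p Probability that the second observer scores a
#'   criterion one ordinal step below the first.
#' @param gag_ug_mg,hyp_ug_mg Named vectors (zones) of mean tissue GAG /
#'   hydroxyproline content, ug per mg wet weight.
#' @param gag_cv,hyp_cv Between-animal coefficient of variation of the
#'   zonal contents.
#' @param expr_mult Named vector over [QPCR_GENES] of expression
#'   multipliers vs the NOC baseline (applied in every zone).
#' @param expr_sdlog Between-animal log-normal sd of expression.
#' @param scheme A [scoring_scheme()] used to validate the score means.
#' @return A `cohort_preset` object.
#' @export
cohort_preset <- function(name, loop_params,
                          dhi_ratio_mean, dhi_ratio_sd,
                          histo_criterion_means, histo_criterion_sd,
                          observer_jitter_p = 0.3,
                          gag_ug_mg, gag_cv = 0.10,
                          hyp_ug_mg, hyp_cv = 0.08,
                          expr_mult, expr_sdlog = 0.12,
                          scheme = scoring_scheme()) {
  stopifnot(is.list(loop_params),
            all(c("flexion_extension", "lateral_bending", "axial_rotation")
                %in% names(loop_params)))
  if (dhi_ratio_mean <= 0 || dhi_ratio_mean > 1.2)
    stop("dhi_ratio_mean must be in (0, 1.2]", call. = FALSE)
  sds <- c(dhi_ratio_sd, histo_criterion_sd, gag_cv, hyp_cv, expr_sdlog)
  if (any(sds < 0)) stop("all dispersions must be >= 0", call. = FALSE)
  if (observer_jitter_p < 0 || observer_jitter_p > 1)
    stop("observer_jitter_p must be a probability", call. = FALSE)
  m <- histo_criterion_means[HISTO_CRITERIA]
  if (anyNA(m)) stop("histo_criterion_means must cover all criteria",
                     call. = FALSE)
  if (any(m < 0) || any(m > scheme$max_scores))
    stop("criterion mean outside scheme range", call. = FALSE)
  if (!setequal(names(expr_mult), QPCR_GENES) || any(expr_mult <= 0))
    stop("expr_mult must be positive and cover the gene panel", call. = FALSE)
  if (!setequal(names(gag_ug_mg), names(hyp_ug_mg)))
    stop("gag and hydroxyproline zones differ", call. = FALSE)
  out <- list(name = name, loop_params = loop_params,
              dhi_ratio_mean = dhi_ratio_mean, dhi_ratio_sd = dhi_ratio_sd,
              histo_criterion_means = m,
              histo_criterion_sd = histo_criterion_sd,
              observer_jitter_p = observer_jitter_p,
              gag_ug_mg = gag_ug_mg, gag_cv = gag_cv,
              hyp_ug_mg = hyp_ug_mg, hyp_cv = hyp_cv,
              expr_mult = expr_mult[QPCR_GENES], expr_sdlog = expr_sdlog,
              scheme = scheme)
  class(out) <- "cohort_preset"
  out
}

#' Default cohort presets calibrated to the emulated study
#'
#' Four presets: `"NOC"` (nonoperated control), `"degenerate-baseline"`
#' (lesion disc before injection), `"PBS-endpoint"` (carrier-injected
#' lesion disc at sacrifice) and `"MSC-endpoint"` (stem-cell-treated disc
#' at sacrifice). Histopathology criterion means are allocated so the
#' cumulative-score expectations equal the cohort means of the emulated
#' study (NOC 2, degenerate baseline 22, PBS endpoint 19, MSC endpoint 4;
#' per-criterion dispersion = cohort SD / sqrt(6)); disc-height ratios give
#' cohort mean percent DHI of 100, 85, 80 and 93.5 respectively. The
#' per-criterion allocation and the biochemical/expression magnitudes are
#' design choices documented in the methods vignette.
#'
#' @return Named list of [cohort_preset()] objects.
#' @export
default_presets <- function() {
  hp <- hysteresis_params
  crit <- function(x) stats::setNames(x, HISTO_CRITERIA)
  genes <- function(...) {
    v <- c(...)
    base <- stats::setNames(rep(1, length(QPCR_GENES)), QPCR_GENES)
    base[names(v)] <- v
    base
  }
  catabolic_up <- genes(COL1A1 = 2, COL2A1 = 0.5, ACAN = 0.5, IL1RN = 3,
                        MMP2 = 3, MMP3 = 5, MMP9 = 4, MMP13 = 6,
                        ADAMTS4 = 4, ADAMTS5 = 3)
  list(
    "NOC" = cohort_preset(
      "NOC",
      loop_params = list(
        flexion_extension = hp(0.020, 3.0, 3.0),
        lateral_bending   = hp(0.025, 3.2, 2.5),
        axial_rotation    = hp(0.40, 2.5, 2.0)),
      dhi_ratio_mean = 1.00, dhi_ratio_sd = 0.010,
      histo_criterion_means = crit(c(1, 1, 0, 0, 0, 0)),
      histo_criterion_sd = 0.30,
      gag_ug_mg = c(AF1 = 20, AF2 = 28, NP = 45),
      hyp_ug_mg = c(AF1 = 18, AF2 = 15, NP = 6),
      expr_mult = genes()),
    "degenerate-baseline" = cohort_preset(
      "degenerate-baseline",
      loop_params = list(
        flexion_extension = hp(0.015, 2.2, 4.5),
        lateral_bending   = hp(0.020, 2.4, 4.0),
        axial_rotation    = hp(0.35, 2.2, 2.0)),
      dhi_ratio_mean = 0.85, dhi_ratio_sd = 0.030,
      histo_criterion_means = crit(c(4, 4, 4, 4, 3, 3)),       # sums to 22
      histo_criterion_sd = 2.2 / sqrt(6),
      gag_ug_mg = c(AF1 = 14, AF2 = 22, NP = 28),
      hyp_ug_mg = c(AF1 = 18, AF2 = 15, NP = 6),
      expr_mult = catabolic_up),
    "PBS-endpoint" = cohort_preset(
      "PBS-endpoint",
      loop_params = list(
        flexion_extension = hp(0.015, 2.2, 4.5),
        lateral_bending   = hp(0.020, 2.4, 4.0),
        axial_rotation    = hp(0.35, 2.2, 2.0)),
      dhi_ratio_mean = 0.80, dhi_ratio_sd = 0.030,
      histo_criterion_means = crit(c(4, 4, 3, 3, 3, 2)),       # sums to 19
      histo_criterion_sd = 2.5 / sqrt(6),
      gag_ug_mg = c(AF1 = 12, AF2 = 20, NP = 25),
      hyp_ug_mg = c(AF1 = 18, AF2 = 15, NP = 6.5),
      expr_mult = catabolic_up),
    "MSC-endpoint" = cohort_preset(
      "MSC-endpoint",
      loop_params = list(
        flexion_extension = hp(0.020, 2.8, 3.2),
        lateral_bending   = hp(0.024, 3.0, 2.7),
        axial_rotation    = hp(0.40, 2.4, 2.0)),
      dhi_ratio_mean = 0.935, dhi_ratio_sd = 0.015,
      histo_criterion_means = crit(c(1, 1, 1, 1, 0, 0)),       # sums to 4
      histo_criterion_sd = 0.4 / sqrt(6),
      gag_ug_mg = c(AF1 = 19, AF2 = 27, NP = 42),
      hyp_ug_mg = c(AF1 = 17, AF2 = 14.5, NP = 6),
      expr_mult = genes(COL1A1 = 0.7)))
}

#' Strip all randomness from a preset
#'
#' Returns a copy of the preset with every dispersion, jitter and
#' measurement-noise parameter set to zero, so downstream stages must
#' recover the preset's central values exactly (round-trip checks).
#'
#' @param preset A [cohort_preset()].
#' @return The noise-free preset.
#' @export
zero_noise_preset <- function(preset) {
  stopifnot(inherits(preset, "cohort_preset"))
  preset$dhi_ratio_sd <- 0
  preset$histo_criterion_sd <- 0
  preset$observer_jitter_p <- 0
  preset$gag_cv <- 0
  preset$hyp_cv <- 0
  preset$expr_sdlog <- 0
  preset$loop_params <- lapply(preset$loop_params, function(p) {
    p$noise_sd <- 0
    p
  })
  preset
}

# deterministic per-table child seed: every generator draws from its own
# named substream of the study seed
substream <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
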