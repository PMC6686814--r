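# End-to-end synthetic study: generate every input modality for each
# cohort cell, run all analysis stages, summarise per cohort, compare MSC
# against PBS arms with exact Mann-Whitney tests under study-wide
# Benjamini-Hochberg correction, and report recovery of generator truth.

#' Percent disc height index table from a cohort landmark table
#'
#' @param landmarks Output of [generate_landmarks()] (or any table in that
#'   layout with `pre_surgery` and `endpoint` timepoints).
#' @return Tibble (`sheep`, `disc_level`, `dhi_pre`, `dhi_end`,
#'   `percent_dhi`).
#' @export
dhi_table <- function(landmarks) {
  cells <- unique(landmarks[, c("sheep", "disc_level")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- landmarks[landmarks$sheep == cells$sheep[i] &
                       landmarks$disc_level == cells$disc_level[i], ]
    pre <- sub[sub$timepoint == "pre_surgery", ]
    end <- sub[sub$timepoint == "endpoint", ]
    d_pre <- dhi(pre)$dhi
    d_end <- dhi(end)$dhi
    tibble::tibble(sheep = cells$sheep[i], disc_level = cells$disc_level[i],
                   dhi_pre = d_pre, dhi_end = d_end,
                   percent_dhi = 100 * d_end / d_pre)
  })
  dplyr::bind_rows(out)
}

#' Cumulative histopathology scores of a cohort score sheet
#'
#' Reconciles the two observers per disc and sums the six criteria.
#'
#' @param profiles Output of [generate_histo_profiles()] (long score
#'   sheet).
#' @param scheme A [scoring_scheme()].
#' @return Tibble (`disc`, `sheep`, `cumulative`, `mean_disagreement`).
#' @export
histo_cumulative_table <- function(profiles, scheme = scoring_scheme()) {
  out <- lapply(split(profiles, profiles$disc), function(d) {
    cons <- reconcile_observers(d, scheme)
    tibble::tibble(disc = d$disc[1], sheep = d$sheep[1],
                   cumulative = cumulative_score(
                     stats::setNames(cons$score, cons$criterion), scheme),
                   mean_disagreement = mean(cons$disagreement))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$sheep)
}

#' Tissue contents from generated plate data
#'
#' Fits the GAG and hydroxyproline standard curves and back-calculates
#' ug/mg wet weight for every sample.
#'
#' @param plate Output of [generate_plate_data()].
#' @return Tibble (`analyte`, `sheep`, `zone`, `ug_per_mg`, `sd_ug_per_mg`,
#'   `extrapolated`).
#' @export
biochem_table <- function(plate) {
  curves <- list(
    GAG = fit_standard_curve(plate$gag_standards$amount_ug,
                             plate$gag_standards$signal, "GAG"),
    hydroxyproline = fit_standard_curve(plate$hyp_standards$amount_ug,
                                        plate$hyp_standards$signal,
                                        "hydroxyproline"))
  cells <- unique(plate$assay_samples[, c("analyte", "sheep", "zone")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- plate$assay_samples[
      plate$assay_samples$analyte == cells$analyte[i] &
        plate$assay_samples$sheep == cells$sheep[i] &
        plate$assay_samples$zone == cells$zone[i], ]
    q <- quantify(sub$signal, sub$wet_weight_mg[1],
                  curves[[cells$analyte[i]]],
                  digest_volume_ml = plate$config$digest_volume_ml,
                  aliquot_volume_ml = plate$config$aliquot_volume_ml)
    tibble::tibble(analyte = cells$analyte[i], sheep = cells$sheep[i],
                   zone = cells$zone[i], ug_per_mg = q$ug_per_mg,
                   sd_ug_per_mg = q$sd_ug_per_mg,
                   extrapolated = q$extrapolated)
  })
  dplyr::bind_rows(out)
}

#' Normalised expression from generated qPCR data
#'
#' @param plate Output of [generate_plate_data()].
#' @return Tibble from [relative_copies()] joined with `sheep` and `zone`.
#' @export
qpcr_table <- function(plate) {
  curves <- lapply(split(plate$dilution_series, plate$dilution_series$gene),
                   function(d) fit_ct_curve(d$copies, d$ct, d$gene[1]))
  rc <- relative_copies(plate$ct_table, curves)
  meta <- unique(plate$ct_table[, c("sample", "sheep", "zone")])
  dplyr::inner_join(rc, meta, by = "sample")
}

#' Biomechanics result table for a cohort
#'
#' @param records Output of [generate_loading_records()].
#' @return Tibble (`sheep`, `mode`, `rom_deg`, `nz_present`,
#'   `nz_width_deg`, `final_stiffness`, plus the generator's analytic
#'   `*_true` values).
#' @export
biomech_table <- function(records) {
  out <- lapply(records, function(rec) {
    res <- analyze_record(rec)
    tibble::tibble(sheep = as.integer(sub("-.*$", "",
                                          sub("^.*-", "", rec$specimen))),
                   mode = rec$loading_mode,
                   rom_deg = res$rom_deg, nz_present = res$nz_present,
                   nz_width_deg = res$nz_width_deg,
                   final_stiffness = res$final_stiffness,
                   rom_true = rec$truth$rom,
                   nz_width_true = rec$truth$nz_width,
                   stiffness_true = rec$truth$stiffness_final)
  })
  dplyr::bind_rows(out)
}

summary_row <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  tibble::tibble(n = sum(!is.na(x)), mean = mean(x, na.rm = TRUE),
                 sd = stats::sd(x, na.rm = TRUE), median = q[2],
                 q25 = q[1], q75 = q[3],
                 min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
}

#' Run a complete synthetic study
#'
#' Generates every input modality for each cohort cell of the design, runs
#' all analysis stages, and assembles: a tidy long endpoint table, cohort
#' summaries (mean, SD and box-plot five-number summaries), MSC-vs-PBS
#' Mann-Whitney comparisons per group with study-wide Benjamini-Hochberg
#' correction, and a ground-truth recovery appendix.
#'
#' @param design A [study_design()].
#' @param presets Named list of [cohort_preset()]s; must contain the names
#'   used by `preset_map`.
#' @param seed Integer study seed driving every substream.
#' @param preset_map Function `(group, arm) -> preset name`.
#' @param alpha False-discovery rate for the correction.
#' @return An `ivdd_study` list: `endpoints` (tidy long table),
#'   `summaries`, `comparisons`, `bh`, `recovery`, `seed`.
#' @export
run_study <- function(design = study_design(), presets = default_presets(),
                      seed = 1,
                      preset_map = function(group, arm) switch(
                        arm, none = "NOC", PBS = "PBS-endpoint",
                        MSC = "MSC-endpoint"),
                      alpha = 0.05) {
  stopifnot(inherits(design, "study_design"))
  cells <- design$cells
  endpoints <- list(); recovery <- list()
  for (i in seq_len(nrow(cells))) {
    group <- cells$group[i]; arm <- cells$arm[i]
    pname <- preset_map(group, arm)
    if (!pname %in% names(presets))
      stop("study stage 'presets': no preset named ", pname, call. = FALSE)
    preset <- presets[[pname]]
    cell_seed <- substream(seed, paste0("cell/", group, "/", arm))
    ep <- function(endpoint, sheep, value, zone = NA_character_)
      tibble::tibble(group = group, arm = arm, sheep = sheep,
                     endpoint = endpoint, zone = zone, value = value)

    histo <- try_stage("histopathology", function() {
      prof <- generate_histo_profiles(preset, design, cell_seed)
      histo_cumulative_table(prof, preset$scheme)
    })
    endpoints[[length(endpoints) + 1]] <-
      ep("cumulative_score", histo$sheep, histo$cumulative)
    recovery[[length(recovery) + 1]] <- tibble::tibble(
      group = group, arm = arm, quantity = "cumulative_score",
      estimate = mean(histo$cumulative),
      truth = sum(preset$histo_criterion_means))

    dh <- try_stage("radiography", function() {
      dhi_table(generate_landmarks(preset, design, cell_seed))
    })
    per_sheep <- dplyr::summarise(dplyr::group_by(dh, .data$sheep),
                                  v = mean(.data$percent_dhi), .groups = "drop")
    endpoints[[length(endpoints) + 1]] <-
      ep("percent_dhi", per_sheep$sheep, per_sheep$v)
    recovery[[length(recovery) + 1]] <- tibble::tibble(
      group = group, arm = arm, quantity = "percent_dhi",
      estimate = mean(dh$percent_dhi),
      truth = 100 * preset$dhi_ratio_mean)

    bm <- try_stage("biomechanics", function() {
      biomech_table(generate_loading_records(preset, design, cell_seed))
    })
    for (mode in unique(bm$mode)) {
      sub <- bm[bm$mode == mode, ]
      endpoints[[length(endpoints) + 1]] <-
        ep(paste0("nz_width_", mode), sub$sheep, sub$nz_width_deg)
      endpoints[[length(endpoints) + 1]] <-
        ep(paste0("stiffness_", mode), sub$sheep, sub$final_stiffness)
      endpoints[[length(endpoints) + 1]] <-
        ep(paste0("rom_", mode), sub$sheep, sub$rom_deg)
      recovery[[length(recovery) + 1]] <- tibble::tibble(
        group = group, arm = arm,
        quantity = c(paste0("nz_width_", mode), paste0("stiffness_", mode)),
        estimate = c(mean(sub$nz_width_deg), mean(sub$final_stiffness)),
        truth = c(sub$nz_width_true[1], sub$stiffness_true[1]))
    }

    plate <- try_stage("plate_data", function()
      generate_plate_data(preset, design, cell_seed))
    bc <- try_stage("biochemistry", function() biochem_table(plate))
    for (analyte in unique(bc$analyte)) for (z in design$zones) {
      sub <- bc[bc$analyte == analyte & bc$zone == z, ]
      endpoints[[length(endpoints) + 1]] <-
        ep(paste0(tolower(substr(analyte, 1, 3)), "_ug_mg"),
           sub$sheep, sub$ug_per_mg, zone = z)
      mu <- if (analyte == "GAG") preset$gag_ug_mg else preset$hyp_ug_mg
      recovery[[length(recovery) + 1]] <- tibble::tibble(
        group = group, arm = arm,
        quantity = paste0(tolower(substr(analyte, 1, 3)), "_", z),
        estimate = mean(sub$ug_per_mg), truth = mu[[z]])
    }

    qp <- try_stage("qpcr", function() qpcr_table(plate))
    for (g in c("MMP3", "ACAN")) {
      sub <- qp[qp$gene == g & qp$zone == "NP", ]
      endpoints[[length(endpoints) + 1]] <-
        ep(paste0("expr_", g), sub$sheep, sub$rel_copies, zone = "NP")
    }
  }
  endpoints <- dplyr::bind_rows(endpoints)

  summaries <- dplyr::bind_rows(lapply(
    split(endpoints,
          paste(endpoints$group, endpoints$arm, endpoints$endpoint,
                endpoints$zone, sep = "|")),
    function(d) dplyr::bind_cols(
      tibble::tibble(group = d$group[1], arm = d$arm[1],
                     endpoint = d$endpoint[1], zone = d$zone[1]),
      summary_row(d$value))))

  comparisons <- list()
  lesion_groups <- setdiff(unique(cells$group), "NOC")
  if (all(c("PBS", "MSC") %in% cells$arm)) {
    for (g in lesion_groups) for (e in unique(endpoints$endpoint)) {
      sub <- endpoints[endpoints$group == g & endpoints$endpoint == e, ]
      for (z in unique(sub$zone)) {
        d <- if (is.na(z)) sub[is.na(sub$zone), ] else
          sub[!is.na(sub$zone) & sub$zone == z, ]
        x <- d$value[d$arm == "MSC"]; y <- d$value[d$arm == "PBS"]
        if (length(x) < 2 || length(y) < 2) next
        mw <- mann_whitney_u(x, y)
        comparisons[[length(comparisons) + 1]] <- tibble::tibble(
          group = g, endpoint = e, zone = z, u = mw$u,
          p_value = mw$p_value, method = mw$method)
      }
    }
  }
  comparisons <- dplyr::bind_rows(comparisons)
  bh <- if (nrow(comparisons) > 0)
    benjamini_hochberg(comparisons$p_value, alpha) else
    benjamini_hochberg(numeric(0), alpha)
  if (nrow(comparisons) > 0) {
    comparisons$p_adjusted <- bh$p_adjusted
    comparisons$significant <- bh$reject
  }

  out <- list(endpoints = endpoints, summaries = summaries,
              comparisons = comparisons, bh = bh,
              recovery = dplyr::bind_rows(recovery), seed = seed)
  class(out) <- "ivdd_study"
  out
}

try_stage <- function(stage, fn) {
  tryCatch(fn(), error = function(e)
    stop("study stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' @export
print.ivdd_study <- function(x, ...) {
  cat("<ivdd_study> seed", x$seed, "\n")
  cat(" ", nrow(x$endpoints), "endpoint values,",
      nrow(x$comparisons), "MSC-vs-PBS comparisons,",
      x$bh$k, "significant after FDR correction")
  if (!is.na(x$bh$threshold))
    cat(" (corrected p threshold", signif(x$bh$threshold, 3), ")")
  cat("\n")
  invisible(x)
}
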