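# Relative copy-number quantitation of a disc matrix gene panel from qPCR
# Ct values. Standard curves come from a dilution series of pooled disc
# cDNA (log-linear model Ct = intercept + slope * log10(copies), copies
# anchored to the top standard = 1). Sample loadings are normalised by
# total RNA content rather than by housekeeping genes, whose expression
# shifts with disc disease.

#' The gene panel quantified from disc tissue
#' @export
QPCR_GENES <- c("COL1A1", "COL2A1", "ACAN", "IL1RN", "MMP2", "MMP3", "MMP9",
                "MMP13", "ADAMTS4", "ADAMTS5", "TIMP1", "TIMP3")

#' Fit a qPCR standard curve from a dilution series
#'
#' @param copies Relative copy numbers of the dilution points (top
#'   standard = 1); at least 3 distinct dilutions.
#' @param ct Measured Ct values.
#' @param gene Gene label.
#' @return A `gene_standard_curve`: `gene`, `slope`, `intercept`,
#'   `efficiency` (`10^(-1/slope) - 1`), `ct_range`.
#' @examples
#' d <- 10^-(0:4)
#' fit_ct_curve(d, 15 - log10(d) / log10(2))$efficiency  # 1 (100%)
#' @export
fit_ct_curve <- function(copies, ct, gene = "gene") {
  stopifnot(length(copies) == length(ct), all(copies > 0), all(ct > 0))
  if (length(unique(copies)) < 3)
    stop("need at least 3 distinct dilutions", call. = FALSE)
  fit <- stats::lm(ct ~ log10(copies))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("non-amplifying standard", call. = FALSE)
  eff <- 10^(-1 / slope) - 1
  if (eff <= 0 || eff > 1.2)
    stop("amplification efficiency outside (0, 1.2]: ", round(eff, 3),
         call. = FALSE)
  out <- list(gene = gene, slope = slope,
              intercept = unname(stats::coef(fit)[1]),
              efficiency = eff, ct_range = range(ct))
  class(out) <- "gene_standard_curve"
  out
}

#' Total-RNA-normalised relative copy numbers from a Ct table
#'
#' Triplicate Ct values are averaged (replicate ranges above `outlier_ct`
#' are flagged), back-transformed through the gene's standard curve and
#' divided by the total-RNA loading of the sample. Mean Ct values outside
#' the standard's Ct range are flagged `out_of_range`.
#'
#' @param ct_table Data frame with columns `sample`, `gene`, `ct`
#'   (replicate rows) and `rna_ug` (total RNA loading, constant within a
#'   sample).
#' @param curves Named list of [fit_ct_curve()] objects, one per gene.
#' @param outlier_ct Replicate-range flag threshold (Ct units).
#' @return Tibble: `sample`, `gene`, `mean_ct`, `rel_copies` (per ug RNA),
#'   `replicate_outlier`, `out_of_range`.
#' @export
relative_copies <- function(ct_table, curves, outlier_ct = 1) {
  need <- c("sample", "gene", "ct", "rna_ug")
  if (!all(need %in% names(ct_table)))
    stop("ct_table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(ct_table$ct <= 0) || any(ct_table$rna_ug <= 0))
    stop("Ct and RNA loadings must be > 0", call. = FALSE)
  missing <- setdiff(unique(ct_table$gene), names(curves))
  if (length(missing))
    stop("missing standard curve for gene: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(ct_table, .data$sample, .data$gene),
    mean_ct = mean(.data$ct),
    replicate_outlier = diff(range(.data$ct)) > outlier_ct,
    rna_ug = .data$rna_ug[1],
    .groups = "drop")
  cv <- curves[out$gene]
  slope <- vapply(cv, `[[`, numeric(1), "slope")
  intercept <- vapply(cv, `[[`, numeric(1), "intercept")
  lo <- vapply(cv, function(c) c$ct_range[1], numeric(1))
  hi <- vapply(cv, function(c) c$ct_range[2], numeric(1))
  out$rel_copies <- unname(10^((out$mean_ct - intercept) / slope) / out$rna_ug)
  out$out_of_range <- unname(out$mean_ct < lo | out$mean_ct > hi)
  out$rna_ug <- NULL
  out
}

#' Fold change of group geometric means against nonoperated controls
#'
#' @param copies_table Output of [relative_copies()] joined with study
#'   metadata; needs columns `group`, `gene`, `rel_copies` and optionally
#'   `zone` (folds are computed within zone when present).
#' @param noc_group Label of the reference group (default `"NOC"`).
#' @return Tibble of `group` (non-reference), `gene` (and `zone`), and
#'   `fold_vs_noc` = geometric mean(group) / geometric mean(reference).
#' @export
fold_vs_noc <- function(copies_table, noc_group = "NOC") {
  need <- c("group", "gene", "rel_copies")
  if (!all(need %in% names(copies_table)))
    stop("needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!noc_group %in% copies_table$group)
    stop("reference group '", noc_group, "' absent", call. = FALSE)
  if (any(copies_table$rel_copies <= 0))
    stop("rel_copies must be > 0 for geometric means", call. = FALSE)
  keys <- intersect(c("gene", "zone", "arm"), names(copies_table))
  gm <- dplyr::summarise(
    dplyr::group_by(copies_table,
                    dplyr::across(dplyr::all_of(c("group", keys)))),
    gmean = exp(mean(log(.data$rel_copies))), .groups = "drop")
  ref <- gm[gm$group == noc_group,
            c(setdiff(keys, "arm"), "gmean"), drop = FALSE]
  names(ref)[names(ref) == "gmean"] <- "gmean_noc"
  out <- dplyr::inner_join(gm[gm$group != noc_group, , drop = FALSE], ref,
                           by = setdiff(keys, "arm"))
  out$fold_vs_noc <- out$gmean / out$gmean_noc
  out$gmean <- out$gmean_noc <- NULL
  out
}
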