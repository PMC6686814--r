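# Standard-curve quantitation of sulfated glycosaminoglycan (DMMB
# dye-binding, chondroitin sulfate standard) and hydroxyproline
# (dimethylaminobenzaldehyde chromogenic assay), expressed per mg wet
# tissue and per dissection zone (outer annulus AF1, inner annulus AF2,
# nucleus pulposus NP). Both assays are used in their linear range, so the
# calibration is an ordinary least-squares line of signal on known amount.

#' Fit a linear standard curve
#'
#' @param amount Known standard amounts (ug); at least 3 distinct values.
#' @param signal Measured signals (absorbance units).
#' @param analyte `"GAG"` or `"hydroxyproline"`.
#' @return A `standard_curve`: `slope`, `intercept`, `r_squared`, `range`
#'   (valid amount range) and `analyte`.
#' @examples
#' sc <- fit_standard_curve(c(0, 10, 20, 40), 0.02 * c(0, 10, 20, 40))
#' sc$slope
#' @export
fit_standard_curve <- function(amount, signal,
                               analyte = c("GAG", "hydroxyproline")) {
  analyte <- match.arg(analyte)
  stopifnot(length(amount) == length(signal))
  if (length(unique(amount)) < 3)
    stop("need at least 3 distinct standard amounts", call. = FALSE)
  fit <- stats::lm(signal ~ amount)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("flat standard curve", call. = FALSE)
  sst <- sum((signal - mean(signal))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  out <- list(slope = slope, intercept = unname(stats::coef(fit)[1]),
              r_squared = r2, range = range(amount), analyte = analyte)
  class(out) <- "standard_curve"
  out
}

#' Back-calculate tissue content from replicate signals
#'
#' Replicate signals are averaged, converted to an amount through the
#' standard curve, corrected for the digested fraction actually assayed
#' (`aliquot_volume / digest_volume`) and divided by the wet weight.
#' Replicate scatter is propagated to a per-sample SD on the ug/mg scale.
#' Amounts outside the standard range are still returned but flagged
#' `extrapolated`; negative back-calculated amounts are clamped to zero
#' with a warning.
#'
#' @param signals Numeric replicate signals (triplicates in the assay
#'   protocol; any length >= 1 accepted).
#' @param wet_weight_mg Wet weight of the digested tissue piece (mg).
#' @param curve A [fit_standard_curve()] object.
#' @param digest_volume_ml,aliquot_volume_ml Digest bookkeeping: total
#'   papain digest volume and the aliquot assayed, so that
#'   `amount_in_tissue = amount_in_aliquot * digest_volume / aliquot_volume`.
#' @return List: `ug_per_mg`, `sd_ug_per_mg`, `amount_ug` (mean aliquot
#'   amount), `extrapolated`.
#' @export
quantify <- function(signals, wet_weight_mg, curve,
                     digest_volume_ml = 1, aliquot_volume_ml = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (wet_weight_mg <= 0) stop("wet weight must be > 0", call. = FALSE)
  if (digest_volume_ml <= 0 || aliquot_volume_ml <= 0 ||
      aliquot_volume_ml > digest_volume_ml)
    stop("invalid digest bookkeeping", call. = FALSE)
  amounts <- (signals - curve$intercept) / curve$slope
  m <- mean(amounts)
  extrapolated <- m < curve$range[1] || m > curve$range[2]
  if (m < 0) {
    if (m < -1e-9 * max(1, curve$range[2]))
      warning("negative back-calculated amount clamped to 0")
    m <- 0
    amounts <- pmax(amounts, 0)
  }
  scale <- (digest_volume_ml / aliquot_volume_ml) / wet_weight_mg
  list(ug_per_mg = m * scale,
       sd_ug_per_mg = if (length(amounts) > 1) stats::sd(amounts) * scale
                      else NA_real_,
       amount_ug = m, extrapolated = extrapolated)
}
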