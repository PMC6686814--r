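# Torque-angle analysis of functional spinal unit loading records: final
# full cycle extraction, range of motion, seventh-order polynomial
# smoothing per loading direction, gradient-threshold neutral zone with
# common-overlap logic, and initial/final stiffness.

#' Extract the final full cycle of a loading record
#'
#' A cycle is complete when it contains both loading directions and its
#' angle excursion spans the record's extremes (within one sample spacing).
#' Analysis uses the last such cycle.
#'
#' @param record A `loading_record` (see [simulate_loop()]) or a data frame
#'   with columns `time_s`, `angle_deg`, `torque_Nm`, `cycle`, `direction`.
#' @return The record restricted to the final complete cycle.
#' @export
extract_final_cycle <- function(record) {
  smp <- record_samples(record)
  spacing <- stats::median(abs(diff(smp$angle_deg)))
  lo <- min(smp$angle_deg) + spacing
  hi <- max(smp$angle_deg) - spacing
  complete <- vapply(split(smp, smp$cycle), function(d) {
    length(unique(d$direction)) == 2 &&
      min(d$angle_deg) <= lo && max(d$angle_deg) >= hi
  }, logical(1))
  if (!any(complete)) stop("incomplete record: no complete cycle", call. = FALSE)
  last <- max(as.integer(names(complete))[complete])
  out <- smp[smp$cycle == last, , drop = FALSE]
  replace_samples(record, out)
}

record_samples <- function(record) {
  smp <- if (inherits(record, "loading_record")) record$samples else record
  need <- c("time_s", "angle_deg", "torque_Nm", "cycle", "direction")
  if (!all(need %in% names(smp)))
    stop("record lacks columns: ", paste(setdiff(need, names(smp)), collapse = ", "),
         call. = FALSE)
  smp
}

replace_samples <- function(record, smp) {
  if (inherits(record, "loading_record")) {
    record$samples <- smp
    record
  } else smp
}

#' Range of motion of a loading cycle
#'
#' Total angular deflection from the angle at maximal positive torque to
#' the angle at minimal negative torque, reported positive.
#'
#' @param cycle A loading record or sample table (normally the output of
#'   [extract_final_cycle()]).
#' @return ROM in degrees.
#' @export
compute_rom <- function(cycle) {
  smp <- record_samples(cycle)
  if (max(smp$torque_Nm) <= 0 || min(smp$torque_Nm) >= 0)
    stop("torque does not change sign; ROM undefined", call. = FALSE)
  abs(smp$angle_deg[which.max(smp$torque_Nm)] -
        smp$angle_deg[which.min(smp$torque_Nm)])
}

#' Fit a seventh-order polynomial to one loading direction
#'
#' Ordinary least squares of torque on angle, degree 7, computed on a
#' centred and scaled angle for numerical conditioning. The fit is only
#' valid on the angle span of the data.
#'
#' @param samples Sample table for a single loading direction.
#' @param degree Polynomial degree (default 7).
#' @return A `direction_fit`: coefficients (scaled space), centring
#'   constants, `domain` (angle span, deg) and `rms` residual (Nm).
#' @export
fit_direction <- function(samples, degree = 7) {
  smp <- if (is.data.frame(samples)) samples else record_samples(samples)
  if (nrow(smp) < degree + 2)
    stop("need at least ", degree + 2, " samples in the direction", call. = FALSE)
  if (length(unique(smp$angle_deg)) < degree + 1)
    stop("rank deficiency: fewer than ", degree + 1, " distinct angles",
         call. = FALSE)
  centre <- mean(range(smp$angle_deg))
  scale <- diff(range(smp$angle_deg)) / 2
  z <- (smp$angle_deg - centre) / scale
  fit <- stats::lm(smp$torque_Nm ~ stats::poly(z, degree, raw = TRUE))
  beta <- unname(stats::coef(fit))
  if (anyNA(beta)) stop("rank deficiency in polynomial fit", call. = FALSE)
  out <- list(coef = beta, centre = centre, scale = scale,
              degree = degree, domain = range(smp$angle_deg),
              rms = sqrt(mean(stats::resid(fit)^2)))
  class(out) <- "direction_fit"
  out
}

#' Evaluate a direction fit or its gradient
#'
#' @param fit A `direction_fit`.
#' @param theta Angle (deg); must lie inside the fit domain.
#' @return Fitted torque (Nm) or gradient (Nm/deg).
#' @export
predict_torque <- function(fit, theta) {
  check_domain(fit, theta)
  z <- (theta - fit$centre) / fit$scale
  drop(outer(z, 0:fit$degree, `^`) %*% fit$coef)
}

#' @rdname predict_torque
#' @export
predict_gradient <- function(fit, theta) {
  check_domain(fit, theta)
  z <- (theta - fit$centre) / fit$scale
  dcoef <- fit$coef[-1] * seq_len(fit$degree)
  drop(outer(z, 0:(fit$degree - 1), `^`) %*% dcoef) / fit$scale
}

check_domain <- function(fit, theta) {
  eps <- 1e-8 * max(1, abs(fit$domain))
  if (any(theta < fit$domain[1] - eps | theta > fit$domain[2] + eps))
    stop("evaluation outside fit domain", call. = FALSE)
  invisible(NULL)
}

# zero-torque crossing of a fit nearest the neutral position; NA when the
# fitted torque does not change sign on the grid
zero_crossing <- function(fit, grid) {
  tq <- predict_torque(fit, grid)
  s <- sign(tq)
  flips <- which(s[-1] * s[-length(s)] < 0)
  exact <- which(tq == 0)
  cand <- c(grid[exact],
            vapply(flips, function(i) {
              stats::uniroot(function(th) predict_torque(fit, th),
                             c(grid[i], grid[i + 1]), tol = 1e-10)$root
            }, numeric(1)))
  if (length(cand) == 0) return(NA_real_)
  cand[which.min(abs(cand))]
}

# maximal contiguous runs of TRUE on a grid; returns a list of index ranges
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}

# sub-threshold interval for one direction: the maximal contiguous run
# containing the zero-torque crossing, or the run nearest to it
direction_nz_interval <- function(fit, grid, threshold) {
  grad <- predict_gradient(fit, grid)
  runs <- true_runs(grad < threshold)   # strict <, matching the criterion
  if (length(runs) == 0) return(NULL)
  th0 <- zero_crossing(fit, grid)
  if (is.na(th0)) th0 <- 0
  lohi <- lapply(runs, function(r) grid[r])
  dist <- vapply(lohi, function(iv) {
    if (th0 >= iv[1] && th0 <= iv[2]) 0 else min(abs(iv - th0))
  }, numeric(1))
  lohi[[which.min(dist)]]
}

#' Neutral zone from two per-direction polynomial fits
#'
#' The gradient of each direction fit is evaluated on a dense grid over the
#' shared angle domain; per direction, the neutral zone is the maximal
#' contiguous interval with gradient strictly below `threshold` containing
#' (or nearest to) that direction's zero-torque crossing. The final neutral
#' zone is the common overlapping range of the two per-direction intervals;
#' it is absent if either direction has no sub-threshold region or the
#' overlap is empty.
#'
#' @param fit_pos,fit_neg `direction_fit` objects for the two loading
#'   directions.
#' @param threshold Gradient criterion (Nm/deg), default 0.05.
#' @param grid_step Grid resolution (deg), default 0.01.
#' @return List with `present`, `range` (deg), `width` (deg, 0 when
#'   absent) and `threshold`.
#' @export
neutral_zone <- function(fit_pos, fit_neg,
                         threshold = NZ_GRADIENT_THRESHOLD,
                         grid_step = 0.01) {
  lo <- max(fit_pos$domain[1], fit_neg$domain[1])
  hi <- min(fit_pos$domain[2], fit_neg$domain[2])
  if (lo >= hi) stop("disjoint fit domains", call. = FALSE)
  grid <- seq(lo, hi, by = grid_step)
  iv_pos <- direction_nz_interval(fit_pos, grid, threshold)
  iv_neg <- direction_nz_interval(fit_neg, grid, threshold)
  if (is.null(iv_pos) || is.null(iv_neg))
    return(list(present = FALSE, range = c(NA_real_, NA_real_),
                width = 0, threshold = threshold))
  rng <- c(max(iv_pos[1], iv_neg[1]), min(iv_pos[2], iv_neg[2]))
  if (rng[1] > rng[2])
    return(list(present = FALSE, range = c(NA_real_, NA_real_),
                width = 0, threshold = threshold))
  list(present = TRUE, range = rng, width = diff(rng), threshold = threshold)
}

#' Initial stiffness of one loading direction
#'
#' Gradient of the fitted torque-angle curve at the neutral position (the
#' zero-torque crossing of the fit), averaged over the maximal contiguous
#' interval around it where the gradient deviates from its neutral-position
#' value by less than `delta_threshold`.
#'
#' @param fit A `direction_fit`.
#' @param delta_threshold Allowed gradient change (Nm/deg), default 0.05.
#' @param grid_step Grid resolution (deg), default 0.01.
#' @return Initial stiffness (Nm/deg).
#' @export
stiffness <- function(fit, delta_threshold = NZ_GRADIENT_THRESHOLD,
                      grid_step = 0.01) {
  grid <- seq(fit$domain[1], fit$domain[2], by = grid_step)
  th0 <- zero_crossing(fit, grid)
  if (is.na(th0)) stop("no neutral position", call. = FALSE)
  g0 <- predict_gradient(fit, th0)
  grad <- predict_gradient(fit, grid)
  runs <- true_runs(abs(grad - g0) < delta_threshold)
  i0 <- which.min(abs(grid - th0))
  run <- Filter(function(r) r[1] <= i0 && i0 <= r[2], runs)
  if (length(run) == 0) return(g0)
  idx <- seq(run[[1]][1], run[[1]][2])
  mean(grad[idx])
}

#' Final stiffness: average of the two loading directions
#'
#' @param s_pos,s_neg Per-direction initial stiffnesses (Nm/deg).
#' @return Arithmetic mean (Nm/deg).
#' @export
final_stiffness <- function(s_pos, s_neg) (s_pos + s_neg) / 2

#' Full torque-angle analysis of a loading record
#'
#' Runs the complete procedure: final full cycle, ROM, per-direction
#' seventh-order fits, neutral zone (common overlap at the gradient
#' criterion) and initial/final stiffness.
#'
#' @param record A `loading_record` or sample table.
#' @param threshold Gradient criterion (Nm/deg).
#' @param degree Polynomial degree.
#' @param grid_step Gradient evaluation grid (deg).
#' @return A `biomech_result` list: `rom_deg`, `nz_present`, `nz_range`,
#'   `nz_width_deg`, `stiffness_pos`, `stiffness_neg`,
#'   `final_stiffness`, `threshold_used`, `fit_rms`.
#' @examples
#' rec <- simulate_loop(hysteresis_params(0.02, 3, 3, noise_sd = 0), seed = 1)
#' analyze_record(rec)$nz_width_deg
#' @export
analyze_record <- function(record, threshold = NZ_GRADIENT_THRESHOLD,
                           degree = 7, grid_step = 0.01) {
  cyc <- extract_final_cycle(record)
  smp <- record_samples(cyc)
  rom <- compute_rom(smp)
  fit_pos <- fit_direction(smp[smp$direction == "loading_positive", ], degree)
  fit_neg <- fit_direction(smp[smp$direction == "loading_negative", ], degree)
  nz <- neutral_zone(fit_pos, fit_neg, threshold, grid_step)
  s_pos <- stiffness(fit_pos, threshold, grid_step)
  s_neg <- stiffness(fit_neg, threshold, grid_step)
  out <- list(rom_deg = rom,
              nz_present = nz$present, nz_range = nz$range,
              nz_width_deg = nz$width,
              stiffness_pos = s_pos, stiffness_neg = s_neg,
              final_stiffness = final_stiffness(s_pos, s_neg),
              threshold_used = threshold,
              fit_rms = c(pos = fit_pos$rms, neg = fit_neg$rms))
  class(out) <- "biomech_result"
  out
}

#' @export
print.biomech_result <- function(x, ...) {
  cat("<biomech_result>\n")
  cat("  ROM:", round(x$rom_deg, 3), "deg\n")
  if (x$nz_present) {
    cat("  NZ: [", round(x$nz_range[1], 3), ",", round(x$nz_range[2], 3),
        "] deg, width", round(x$nz_width_deg, 3), "deg\n")
  } else cat("  NZ: absent (no region below", x$threshold_used, "Nm/deg)\n")
  cat("  stiffness:", round(x$stiffness_pos, 4), "/",
      round(x$stiffness_neg, 4), "Nm/deg, final",
      round(x$final_stiffness, 4), "Nm/deg\n")
  invisible(x)
}
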