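# Synthetic torque-angle hysteresis loops for functional spinal unit testing.
#
# The noiseless backbone is a smooth odd dual-stiffness curve
#   T(theta) = k_nz * theta + (k_el - k_nz) * theta^5 / (5 * a^4)
# with gradient
#   T'(theta) = k_nz + (k_el - k_nz) * (theta / a)^4,
# i.e. a flat low-stiffness well of gradient k_nz around the neutral
# position that stiffens progressively towards end range. The transition
# scale `a` is set from `nz_half_width` so that, for a neutral-zone-capable
# mode (k_nz below the 0.05 Nm/deg gradient criterion), the backbone
# gradient crosses the criterion exactly at +/- nz_half_width. Because the
# backbone is itself a quintic, the seventh-order polynomial smoothing used
# downstream represents it exactly, so the closed-form neutral zone and
# stiffness below are exact oracles for the estimators.

#' Reference gradient criterion for the neutral zone (Nm/deg)
#'
#' The angular region where the torque-angle gradient is below this value
#' is the neutral zone; the same value parameterises `nz_half_width` in
#' [hysteresis_params()].
#' @export
NZ_GRADIENT_THRESHOLD <- 0.05

#' Parameters of a synthetic torque-angle hysteresis loop
#'
#' @param k_nz Neutral-zone-region stiffness (Nm/deg), the backbone gradient
#'   at the neutral position. A value at or above the 0.05 Nm/deg criterion
#'   describes a mode with no region of low stiffness (axial rotation).
#' @param k_el Elastic-region stiffness (Nm/deg) at the transition shoulder;
#'   must exceed `k_nz` (or equal it for a purely linear specimen).
#' @param nz_half_width Half-width (deg) of the sub-criterion gradient well.
#'   For `k_nz < 0.05 < k_el` the backbone gradient equals 0.05 Nm/deg at
#'   exactly `+/- nz_half_width`; `0` collapses the backbone to a linear
#'   elastic curve of stiffness `k_el`. In no-neutral-zone modes it is the
#'   angle at which the gradient reaches `k_el`.
#' @param hysteresis_offset Half-separation (Nm) of the loading and
#'   unloading limbs: torque is backbone + offset while the angle increases
#'   and backbone - offset while it decreases.
#' @param torque_limit Torque reversal limit (Nm); cycles span the angle
#'   interval where the loading-limb torque stays within `+/- torque_limit`.
#' @param angular_rate Angular velocity of the sweep (deg/s).
#' @param sample_rate Acquisition rate (Hz).
#' @param n_cycles Number of loading cycles.
#' @param noise_sd Additive Gaussian torque noise (Nm).
#' @return A validated `hysteresis_params` object (list).
#' @examples
#' p <- hysteresis_params(k_nz = 0.02, k_el = 3, nz_half_width = 3)
#' loop_truth(p)$nz_width
#' @export
hysteresis_params <- function(k_nz, k_el, nz_half_width,
                              hysteresis_offset = 0.3,
                              torque_limit = 5,
                              angular_rate = 5,
                              sample_rate = 20,
                              n_cycles = 10,
                              noise_sd = 0.05) {
  stopifnot(is.numeric(k_nz), is.numeric(k_el), is.numeric(nz_half_width))
  if (k_nz < 0 || k_el < k_nz || k_el <= 0)
    stop("require 0 <= k_nz <= k_el and k_el > 0", call. = FALSE)
  if (nz_half_width < 0) stop("nz_half_width must be >= 0", call. = FALSE)
  if (torque_limit <= 0) stop("torque_limit must be > 0", call. = FALSE)
  if (hysteresis_offset < 0 || hysteresis_offset >= torque_limit)
    stop("hysteresis_offset must be in [0, torque_limit)", call. = FALSE)
  if (angular_rate <= 0 || sample_rate <= 0 || n_cycles < 1 || noise_sd < 0)
    stop("invalid acquisition parameters", call. = FALSE)
  p <- list(k_nz = k_nz, k_el = k_el, nz_half_width = nz_half_width,
            hysteresis_offset = hysteresis_offset, torque_limit = torque_limit,
            angular_rate = angular_rate, sample_rate = sample_rate,
            n_cycles = n_cycles, noise_sd = noise_sd)
  class(p) <- "hysteresis_params"
  p
}

# transition scale a of the quintic backbone; Inf flags a linear backbone
transition_scale <- function(p, g = NZ_GRADIENT_THRESHOLD) {
  if (p$nz_half_width <= 0 || p$k_el == p$k_nz) return(Inf)
  if (p$k_nz < g && p$k_el > g) {
    p$nz_half_width * ((p$k_el - p$k_nz) / (g - p$k_nz))^0.25
  } else {
    # no sub-criterion well exists; nz_half_width is the shoulder angle
    p$nz_half_width
  }
}

# linear backbones use k_el when nz_half_width = 0 (pure elastic record),
# k_nz = k_el otherwise
linear_stiffness <- function(p) {
  if (p$k_el == p$k_nz) p$k_el else if (p$nz_half_width <= 0) p$k_el else NA_real_
}

#' Noiseless backbone torque and gradient
#'
#' @param theta Angle (deg), vectorised.
#' @param params A [hysteresis_params()] object.
#' @return Torque (Nm) / gradient (Nm/deg) of the backbone.
#' @export
backbone_torque <- function(theta, params) {
  a <- transition_scale(params)
  if (!is.finite(a)) return(linear_stiffness(params) * theta)
  params$k_nz * theta + (params$k_el - params$k_nz) * theta^5 / (5 * a^4)
}

#' @rdname backbone_torque
#' @export
backbone_gradient <- function(theta, params) {
  a <- transition_scale(params)
  if (!is.finite(a)) return(rep(linear_stiffness(params), length(theta)))
  params$k_nz + (params$k_el - params$k_nz) * (theta / a)^4
}

# angle at which the loading limb reaches the torque limit
peak_angle <- function(params) {
  target <- params$torque_limit - params$hysteresis_offset
  f <- function(th) backbone_torque(th, params) - target
  upper <- 10
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
  if (f(upper) < 0) stop("unreachable torque limit", call. = FALSE)
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Analytic ground truth for a hysteresis parameter set
#'
#' Returns the closed-form values of the quantities the torque-angle
#' estimators target: the peak angle and range of motion, the neutral-zone
#' interval and width at the 0.05 Nm/deg gradient criterion (width 0 when no
#' sub-criterion region exists), and the per-direction initial stiffness,
#' defined as the mean backbone gradient over the contiguous band around the
#' zero-torque crossing of each limb where the gradient deviates from its
#' crossing value by less than 0.05 Nm/deg.
#'
#' @param params A [hysteresis_params()] object.
#' @param threshold Gradient criterion (Nm/deg).
#' @return List with `theta_max`, `rom`, `nz_present`, `nz_range`,
#'   `nz_width`, `stiffness_pos`, `stiffness_neg`, `stiffness_final`.
#' @export
loop_truth <- function(params, threshold = NZ_GRADIENT_THRESHOLD) {
  theta_max <- peak_angle(params)
  a <- transition_scale(params)
  g0 <- backbone_gradient(0, params)

  if (g0 >= threshold) {
    nz <- list(present = FALSE, range = c(NA_real_, NA_real_), width = 0)
  } else if (!is.finite(a) || params$k_el <= threshold) {
    # gradient below criterion over the whole record
    nz <- list(present = TRUE, range = c(-theta_max, theta_max),
               width = 2 * theta_max)
  } else {
    half <- a * ((threshold - params$k_nz) / (params$k_el - params$k_nz))^0.25
    half <- min(half, theta_max)
    nz <- list(present = TRUE, range = c(-half, half), width = 2 * half)
  }

  stiff <- function(dir) {
    # zero-torque crossing of the limb backbone +/- offset
    off <- dir * params$hysteresis_offset
    if (off == 0) {
      th0 <- 0
    } else {
      f <- function(th) backbone_torque(th, params) + off
      th0 <- stats::uniroot(f, c(-theta_max, theta_max), tol = 1e-12)$root
    }
    gth0 <- backbone_gradient(th0, params)
    if (!is.finite(a)) return(gth0)
    # the gradient is even and the backbone odd, so the band around -|th0|
    # yields the same mean gradient as the band around +|th0|
    delta <- params$k_el - params$k_nz
    q <- (abs(th0) / a)^4
    qlo <- q - threshold / delta
    qhi <- q + threshold / delta
    hi <- min(a * qhi^0.25, theta_max)
    lo <- if (qlo <= 0) max(-a * qhi^0.25, -theta_max) else a * qlo^0.25
    (backbone_torque(hi, params) - backbone_torque(lo, params)) / (hi - lo)
  }
  s_pos <- stiff(1)
  s_neg <- stiff(-1)
  list(theta_max = theta_max, rom = 2 * theta_max,
       nz_present = nz$present, nz_range = nz$range, nz_width = nz$width,
       stiffness_pos = s_pos, stiffness_neg = s_neg,
       stiffness_final = (s_pos + s_neg) / 2)
}

#' Simulate a cyclic torque-angle loading record
#'
#' Emulates cyclic testing of a functional spinal unit: a triangular angle
#' sweep at `angular_rate` between the angles where the loading-limb torque
#' reaches `+/- torque_limit`, sampled at `sample_rate` for `n_cycles`
#' cycles. Torque is the smooth dual-stiffness backbone plus
#' `+/- hysteresis_offset` by direction of motion and additive Gaussian
#' noise. The analytic ground truth ([loop_truth()]) travels with the
#' record.
#'
#' @param params A [hysteresis_params()] object.
#' @param seed Integer seed; the record is bit-reproducible given
#'   `params` and `seed`.
#' @param specimen Specimen label.
#' @param loading_mode One of `"flexion_extension"`, `"lateral_bending"`,
#'   `"axial_rotation"`.
#' @return A `loading_record`: list with `samples` (tibble: `time_s`,
#'   `angle_deg`, `torque_Nm`, `cycle`, `direction`), `specimen`,
#'   `loading_mode`, `torque_limit`, `params` and `truth`.
#' @examples
#' rec <- simulate_loop(hysteresis_params(0.02, 3, 3, noise_sd = 0), seed = 1)
#' range(rec$samples$cycle)
#' @export
simulate_loop <- function(params, seed,
                          specimen = "S1",
                          loading_mode = c("flexion_extension",
                                           "lateral_bending",
                                           "axial_rotation")) {
  stopifnot(inherits(params, "hysteresis_params"))
  loading_mode <- match.arg(loading_mode)
  truth <- loop_truth(params)
  theta_max <- truth$theta_max

  period <- 4 * theta_max / params$angular_rate
  t <- seq(0, params$n_cycles * period, by = 1 / params$sample_rate)
  t <- t[t < params$n_cycles * period + 1e-12]
  phase <- (t %% period) / period
  # triangle wave: 0 -> +theta_max -> -theta_max -> 0 each cycle
  angle <- ifelse(phase < 0.25, 4 * phase,
           ifelse(phase < 0.75, 2 - 4 * phase, 4 * phase - 4)) * theta_max
  direction <- ifelse(phase < 0.25 | phase >= 0.75,
                      "loading_positive", "loading_negative")
  cycle <- pmin(floor(t / period) + 1L, params$n_cycles)

  torque <- backbone_torque(angle, params) +
    ifelse(direction == "loading_positive", 1, -1) * params$hysteresis_offset
  if (params$noise_sd > 0) {
    old <- withr_seed(seed)
    torque <- torque + stats::rnorm(length(torque), 0, params$noise_sd)
    restore_seed(old)
  }

  rec <- list(samples = tibble::tibble(time_s = t, angle_deg = angle,
                                       torque_Nm = torque, cycle = cycle,
                                       direction = direction),
              specimen = specimen, loading_mode = loading_mode,
              torque_limit = params$torque_limit,
              params = params, truth = truth)
  class(rec) <- "loading_record"
  rec
}

#' @export
print.loading_record <- function(x, ...) {
  cat("<loading_record>", x$specimen, x$loading_mode, "\n")
  cat(" ", nrow(x$samples), "samples,", max(x$samples$cycle), "cycles,",
      "torque limit +/-", x$torque_limit, "Nm\n")
  cat("  ground truth: ROM", round(x$truth$rom, 3), "deg, NZ width",
      round(x$truth$nz_width, 3), "deg\n")
  invisible(x)
}

# local seed handling so generators do not disturb the caller's RNG state
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
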