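# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms and estimator code paths.

# neutral-zone width by brute-force finite differences of the noiseless
# backbone on a dense grid
oracle_nz_fd <- function(params, threshold = 0.05, step = 0.001) {
  theta_max <- ivdd::loop_truth(params)$theta_max
  grid <- seq(-theta_max, theta_max, by = step)
  tq <- ivdd::backbone_torque(grid, params)
  grad <- diff(tq) / diff(grid)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  sub <- grad < threshold
  if (!any(sub)) return(0)
  r <- rle(sub)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  i0 <- which.min(abs(mid))
  hit <- which(runs[, 1] <= i0 & i0 <= runs[, 2])
  if (length(hit) == 0) {
    d <- pmin(abs(mid[runs[, 1]]), abs(mid[runs[, 2]]))
    hit <- which.min(d)
  }
  mid[runs[hit[1], 2]] - mid[runs[hit[1], 1]]
}

# exact two-sided Mann-Whitney p by direct enumeration, with U recomputed
# per assignment from the pair-counting definition (not from ranks)
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(x, y) - mu)
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= obs - 1e-9)
}

# sample table of one loading direction drawn exactly from a polynomial
# torque(angle) = sum(coefs[k] * angle^(k-1))
poly_direction_samples <- function(coefs, domain, n = 200,
                                   direction = "loading_positive") {
  angle <- seq(domain[1], domain[2], length.out = n)
  torque <- drop(outer(angle, seq_along(coefs) - 1, "^") %*% coefs)
  tibble::tibble(time_s = seq_along(angle) / 20, angle_deg = angle,
                 torque_Nm = torque, cycle = 1L, direction = direction)
}

# full named histopathology profile
histo_profile <- function(scores) {
  stats::setNames(scores, ivdd::HISTO_CRITERIA)
}

small_design <- function(n = 6) {
  ivdd::study_design(n_sheep_per_cell = n)
}
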