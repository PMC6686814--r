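# Nonparametric group comparisons for the study endpoints: Mann-Whitney U
# with midrank ties, exact two-sided p by full enumeration of group
# assignments for small samples (a tie-corrected normal approximation
# otherwise), and the Benjamini-Hochberg step-up false-discovery
# correction.

#' Mann-Whitney U test with exact enumeration for small samples
#'
#' U is computed from midranks. When `n1 * n2 <= exact_cap` the two-sided p
#' is exact: every assignment of the pooled observations to the two groups
#' is enumerated and p is the proportion of assignments whose U deviates
#' from the null mean `n1 * n2 / 2` at least as far as the observed U
#' (valid under ties, where the permutation null conditions on the observed
#' pooled values). Larger samples use the tie-corrected normal
#' approximation with continuity correction. Identical pooled values in
#' both samples give p = 1, flagged degenerate.
#'
#' @param x,y Numeric samples (nonempty).
#' @param exact_cap Largest `n1 * n2` for which the exact enumeration is
#'   used (default 100, i.e. up to 10 vs 10).
#' @return A `comparison_result` list: `u` (U statistic of `x`), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`, `degenerate`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 exactly
#' @export
mann_whitney_u <- function(x, y, exact_cap = 100) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)   # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  degenerate <- length(unique(pooled)) == 1
  if (degenerate) {
    res <- list(u = u, p_value = 1, method = "degenerate",
                n1 = n1, n2 = n2, degenerate = TRUE)
    class(res) <- "comparison_result"
    return(res)
  }
  if (n1 * n2 <= exact_cap) {
    p <- exact_mwu_p(r, n1)
    method <- "exact"
  } else {
    p <- approx_mwu_p(u, r, n1, n2)
    method <- "normal_approx"
  }
  res <- list(u = u, p_value = p, method = method,
              n1 = n1, n2 = n2, degenerate = FALSE)
  class(res) <- "comparison_result"
  res
}

# exact two-sided p over all choose(n, n1) group assignments of the pooled
# midranks; two-sided by |U - n1 n2 / 2|
exact_mwu_p <- function(r, n1) {
  n <- length(r)
  n2 <- n - n1
  mu <- n1 * n2 / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  sets <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= obs - 1e-9)
}

# tie-corrected normal approximation with continuity correction
approx_mwu_p <- function(u, r, n1, n2) {
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> U =", x$u, " p =", signif(x$p_value, 4),
      " (", x$method, ", n =", x$n1, "vs", x$n2, ")\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up false-discovery correction
#'
#' Sorts the p-values ascending, finds the largest k with
#' `p_(k) <= k * alpha / m`, rejects hypotheses 1..k and reports the
#' corrected significance threshold `p_(k)`. Adjusted p-values are the
#' standard monotone BH adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Target false-discovery rate (default 0.05).
#' @return List: `p_adjusted` (in input order), `reject` (logical, input
#'   order), `k` (number of rejections), `threshold` (corrected p
#'   threshold, `NA` when nothing is rejected), `alpha`, `m`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.04, 0.30))$k  # 3
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (length(p) == 0)
    return(list(p_adjusted = numeric(0), reject = logical(0), k = 0L,
                threshold = NA_real_, alpha = alpha, m = 0L))
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * alpha / m)
  k <- if (length(below)) max(below) else 0L
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  list(p_adjusted = stats::p.adjust(p, method = "BH"),
       reject = reject, k = as.integer(k),
       threshold = if (k > 0) ps[k] else NA_real_,
       alpha = alpha, m = m)
}
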