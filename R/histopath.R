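# Cumulative histopathology scoring of disc sections: six ordinal criteria
# (toluidine-blue GAG staining, lesion structure, cell morphology, blood
# vessel ingrowth, cellular infiltration, special degenerative/repair
# features), scored per disc by two blinded observers and summed to a
# cumulative score.

#' The six histopathology criteria
#' @export
HISTO_CRITERIA <- c("a_gag_staining", "b_structure", "c_cell_morphology",
                    "d_vessel_ingrowth", "e_cell_infiltration",
                    "f_special_features")

#' Define an ordinal histopathology scoring scheme
#'
#' @param max_scores Named integer vector of per-criterion maxima over the
#'   criteria in [HISTO_CRITERIA]; scores run 0..max. Default 0-5 per
#'   criterion (scheme maximum 30), consistent with cohort cumulative
#'   means up to the low twenties. Ranges are configuration, not
#'   hard-coded, because published schemes differ per criterion.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(max_scores = stats::setNames(rep(5L, 6L),
                                                        HISTO_CRITERIA)) {
  if (is.null(names(max_scores)) || anyDuplicated(names(max_scores)))
    stop("max_scores must be uniquely named", call. = FALSE)
  if (!setequal(names(max_scores), HISTO_CRITERIA))
    stop("criteria must be exactly: ", paste(HISTO_CRITERIA, collapse = ", "),
         call. = FALSE)
  if (any(max_scores < 1) || any(max_scores != round(max_scores)))
    stop("per-criterion maxima must be integers >= 1", call. = FALSE)
  out <- list(max_scores = max_scores[HISTO_CRITERIA],
              scheme_max = sum(max_scores))
  class(out) <- "scoring_scheme"
  out
}

check_profile <- function(scores, scheme) {
  if (is.null(names(scores)))
    stop("scores must be named by criterion", call. = FALSE)
  missing <- setdiff(HISTO_CRITERIA, names(scores))
  if (length(missing))
    stop("missing criterion: ", paste(missing, collapse = ", "), call. = FALSE)
  s <- scores[HISTO_CRITERIA]
  bad <- s < 0 | s > scheme$max_scores | s != round(s)
  if (any(bad))
    stop("score out of range for criterion: ",
         paste(HISTO_CRITERIA[bad], collapse = ", "), call. = FALSE)
  s
}

#' Cumulative histopathology score of one profile
#'
#' Sum of the six per-criterion ordinal scores.
#'
#' @param scores Named numeric vector of per-criterion scores (names as in
#'   [HISTO_CRITERIA]).
#' @param scheme A [scoring_scheme()].
#' @return Integer cumulative score.
#' @examples
#' cumulative_score(c(a_gag_staining = 4, b_structure = 5,
#'                    c_cell_morphology = 3, d_vessel_ingrowth = 4,
#'                    e_cell_infiltration = 3, f_special_features = 3))
#' @export
cumulative_score <- function(scores, scheme = scoring_scheme()) {
  sum(check_profile(scores, scheme))
}

#' Reconcile the score sheets of several observers for one disc
#'
#' Consensus is the per-criterion mean across observers, rounded half-up to
#' the ordinal grid; the per-criterion absolute disagreement (max - min) is
#' recorded alongside.
#'
#' @param profiles Data frame with columns `disc`, `observer`, `criterion`,
#'   `score` for a single disc.
#' @param scheme A [scoring_scheme()].
#' @return Tibble with columns `disc`, `criterion`, `score` (consensus) and
#'   `disagreement`.
#' @export
reconcile_observers <- function(profiles, scheme = scoring_scheme()) {
  need <- c("disc", "observer", "criterion", "score")
  if (!all(need %in% names(profiles)))
    stop("profiles need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (length(unique(profiles$disc)) != 1)
    stop("conflicting disc ids in profiles", call. = FALSE)
  for (obs in split(profiles, profiles$observer))
    check_profile(stats::setNames(obs$score, obs$criterion), scheme)
  agg <- stats::aggregate(score ~ criterion, data = profiles, FUN = mean)
  dis <- stats::aggregate(score ~ criterion, data = profiles,
                          FUN = function(s) max(s) - min(s))
  ord <- match(HISTO_CRITERIA, agg$criterion)
  tibble::tibble(disc = profiles$disc[1],
                 criterion = HISTO_CRITERIA,
                 score = round_half_up(agg$score[ord]),
                 disagreement = dis$score[ord])
}

# round half away from zero on the ordinal grid (2.5 -> 3)
round_half_up <- function(x) floor(x + 0.5)

#' Cohort summary of cumulative histopathology scores
#'
#' Mean, SD and box-plot five-number summary (median, quartiles, range) of
#' the per-disc cumulative scores in one (group, arm) cell. Quartiles use
#' the default continuous quantile definition (type 7).
#'
#' @param scores Numeric vector of per-disc cumulative scores (>= 2).
#' @return Tibble with `n`, `mean`, `sd`, `median`, `q25`, `q75`, `min`,
#'   `max`.
#' @export
cohort_scores <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 discs in the cell", call. = FALSE)
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(n = length(scores), mean = mean(scores),
                 sd = stats::sd(scores), median = q[2], q25 = q[1],
                 q75 = q[3], min = min(scores), max = max(scores))
}
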