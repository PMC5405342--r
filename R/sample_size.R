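# Expected enrolment and early-termination probability under the two
# stage-1 stopping conventions.

.match_mode <- function(mode) {
  match.arg(mode, c("futility_and_go", "futility_only"))
}

# Stage-1 continuation probabilities per stratum. Under "futility_and_go" the
# trial also stops at stage 1 when the cumulative threshold is already met
# (an early go), so the continuation events are truncated above; under
# "futility_only" any count at or above the futility threshold continues.
.stage1_continuation <- function(d, p_neg, p_pos, mode) {
  if (mode == "futility_and_go") {
    p_cont_unsel <- binom_below(d$k_neg, d$N1_neg, p_neg) -
      binom_below(d$k1_neg, d$N1_neg, p_neg)
    p_pos_cont <- binom_below(d$ke_pos, d$N1_pos, p_pos) -
      binom_below(d$k1_pos, d$N1_pos, p_pos)
  } else {
    p_cont_unsel <- binom_tail(d$k1_neg, d$N1_neg, p_neg)
    p_pos_cont <- binom_tail(d$k1_pos, d$N1_pos, p_pos)
  }
  list(unselected = p_cont_unsel,
       enriched = binom_below(d$k1_neg, d$N1_neg, p_neg) * p_pos_cont)
}

#' Expected sample size of the design
#'
#' The trial enrols `N1` participants at stage 1 and, if it continues,
#' either `N2` more (unselected cohort) or `N2e_pos` more (enriched cohort):
#' \deqn{E(N) = N_1 + N_2\,P(\text{continue unselected}) +
#'   N_{2e}^+\,P(\text{continue enriched}).}
#'
#' Two stage-1 stopping conventions are supported, because both appear in
#' practice for this design family:
#'
#' * `"futility_and_go"` (default): the trial also stops at stage 1 when a
#'   stratum's stage-1 count already meets its cumulative threshold (an early
#'   go decision). Continuation events are
#'   \eqn{k_1^- \le X_1^- < k^-} and, after negative-stratum futility,
#'   \eqn{k_1^+ \le X_1^+ < k_e^+}.
#' * `"futility_only"`: the original convention in which stage 1 can only
#'   stop for futility; the upper truncations are removed, i.e. the
#'   continuation events are \eqn{X_1^- \ge k_1^-} and (after futility)
#'   \eqn{X_1^+ \ge k_1^+}.
#'
#' An early go decision only reclassifies *when* the positive outcome is
#' declared, so the route rejection probabilities are identical under the two
#' conventions; only enrolment (and hence `E(N)` and the early-termination
#' probability) differs.
#'
#' @param d A [stratified_design()] (or design string).
#' @param p_neg,p_pos True response rates per stratum.
#' @param mode Stopping convention, see Details.
#' @return An object of class `sample_size_summary`: a list with
#'   `expected_n`, `pet` (probability the trial stops at stage 1),
#'   `p_continue_unselected`, `p_continue_enriched` and `mode`.
#' @examples
#' d <- parse_design("(2 1)/(34 14) -> (5/50) | (4 4)/(53 27)")
#' expected_sample_size(d, 0.03, 0.03, mode = "futility_only")$expected_n  # 65.79
#' @export
expected_sample_size <- function(d, p_neg, p_pos,
                                 mode = c("futility_and_go", "futility_only")) {
  d <- .check_design(d)
  .check_rate(p_neg, "p_neg"); .check_rate(p_pos, "p_pos")
  mode <- .match_mode(mode)
  sz <- design_sizes(d)
  pc <- .stage1_continuation(d, p_neg, p_pos, mode)
  structure(list(
    expected_n = sz$N1 + sz$N2 * pc$unselected + sz$N2e_pos * pc$enriched,
    pet = 1 - pc$unselected - pc$enriched,
    p_continue_unselected = pc$unselected,
    p_continue_enriched = pc$enriched,
    mode = mode), class = "sample_size_summary")
}

#' @export
print.sample_size_summary <- function(x, ...) {
  cat(sprintf("E(N) = %.2f  [mode: %s]\n", x$expected_n, x$mode))
  cat(sprintf("  PET = %.3f; P(continue unselected) = %.3f; P(continue enriched) = %.3f\n",
              x$pet, x$p_continue_unselected, x$p_continue_enriched))
  invisible(x)
}

#' Probability of early termination
#'
#' The probability that the trial stops at stage 1 under the
#' futility-plus-efficacy stopping convention — either an early go in the
#' negative stratum, or negative-stratum futility followed by an early go or
#' futility stop in the positive stratum:
#' \deqn{PET = P(X_1^- \ge k^-) + P(X_1^- < k_1^-)\,
#'   [\,P(X_1^+ \ge k_e^+) + P(X_1^+ < k_1^+)\,].}
#' The negative-futility factor multiplies both positive-stratum stop events,
#' since the positive stratum is only examined after negative-stratum
#' futility.
#'
#' @inheritParams expected_sample_size
#' @return A single probability.
#' @examples
#' d <- parse_design("(3 2)/(44 34) -> (7/104) | (9 4)/(135 53)")
#' early_termination_probability(d, 0.03, 0.03)  # 0.623
#' @export
early_termination_probability <- function(d, p_neg, p_pos) {
  d <- .check_design(d)
  .check_rate(p_neg, "p_neg"); .check_rate(p_pos, "p_pos")
  binom_tail(d$k_neg, d$N1_neg, p_neg) +
    binom_below(d$k1_neg, d$N1_neg, p_neg) *
      (binom_tail(d$ke_pos, d$N1_pos, p_pos) +
         binom_below(d$k1_pos, d$N1_pos, p_pos))
}

#' Probability of a stage-1 go decision for the unselected population
#'
#' `P(X1- >= k_neg)`: the chance that the stage-1 negative-stratum count
#' already meets the cumulative threshold, so the trial can declare the
#' treatment effective in the unselected population at the interim analysis.
#' For well-calibrated designs this probability is tiny under the null.
#'
#' @param d A [stratified_design()] (or design string).
#' @param p_neg Negative-stratum response rate (vectorised).
#' @return Probability vector.
#' @export
stage1_unselected_go_probability <- function(d, p_neg) {
  d <- .check_design(d)
  .check_rate(p_neg, "p_neg")
  binom_tail(d$k_neg, d$N1_neg, p_neg)
}
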