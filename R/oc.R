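# Exact binomial operating characteristics of the stratified
# adaptive-enrichment design: route rejection probabilities, familywise
# error, power, outcome table and rejection curves.

# P(X >= k) for X ~ Binomial(n, p). pbinom(lower.tail = FALSE) sums the upper
# tail directly, so extreme tails keep full relative precision (no 1 - CDF
# cancellation). k <= 0 gives 1; k > n gives 0; n = 0 is the point mass at 0.
binom_tail <- function(k, n, p) {
  if (k <= 0) return(rep(1, length(p)))
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

# P(X < k); k <= 0 gives 0.
binom_below <- function(k, n, p) {
  if (k <= 0) return(rep(0, length(p)))
  stats::pbinom(k - 1, n, p)
}

# Shared kernel for the stage-2 unselected continuation sum. For each stage-1
# negative count i in the continuation region k1- <= i <= min(N1-, k- - 1),
# accumulates f(k- - i, N2-) * P(X1- = i). `tail_fun` is binom_tail for the
# go branch (route 1) and binom_below for the fail branch (route 2 factor).
# An empty continuation region contributes exactly 0.
.neg_continuation_sum <- function(d, p_neg, tail_fun) {
  hi <- min(d$N1_neg, d$k_neg - 1)
  if (hi < d$k1_neg) return(rep(0, length(p_neg)))
  N2_neg <- d$N_neg - d$N1_neg
  out <- rep(0, length(p_neg))
  for (i in d$k1_neg:hi)
    out <- out + tail_fun(d$k_neg - i, N2_neg, p_neg) *
      stats::dbinom(i, d$N1_neg, p_neg)
  out
}

#' Route rejection probabilities
#'
#' Exact probabilities of the three positive trial outcomes:
#'
#' * **Route 1** — the stage-1 negative-stratum count reaches `k1_neg`, the
#'   trial continues with an unselected cohort, and the cumulative negative
#'   count reaches `k_neg` (or already reached it at stage 1): both null
#'   hypotheses are rejected. Depends on `p_neg` only:
#'   \deqn{R_1(p^-) = \sum_{i=k_1^-}^{\min(N_1^-,\,k^- - 1)}
#'     P(X_2^- \ge k^- - i)\,P(X_1^- = i) + P(X_1^- \ge k^-).}
#' * **Route 2** — the unselected stage 2 fails in the negative stratum but
#'   the cumulative positive-stratum count reaches `k_pos`: only the
#'   positive-stratum null is rejected.
#'   \deqn{R_2(p^-, p^+) = P(X^+ \ge k^+) \sum_{i=k_1^-}^{\min(N_1^-,\,k^- - 1)}
#'     P(X_2^- < k^- - i)\,P(X_1^- = i).}
#' * **Route 3** — stage-1 futility in the negative stratum, the positive
#'   stratum continues enriched, and the cumulative positive count reaches
#'   `ke_pos` (possibly already at stage 1):
#'   \deqn{R_3(p^-, p^+) = P(X_1^- < k_1^-)\Big[
#'     \sum_{i=k_1^+}^{\min(N_1^+,\,k_e^+ - 1)}
#'     P(X_{2e}^+ \ge k_e^+ - i)\,P(X_1^+ = i) + P(X_1^+ \ge k_e^+)\Big].}
#'
#' The stage-1 futility factor in Route 3 multiplies *both* bracketed terms:
#' the positive stratum is only examined after negative-stratum futility.
#' All responder counts are binomial with the stated stratum sizes and rates;
#' empty summation ranges contribute 0. Rates exactly 0 or 1 are handled by
#' the corresponding point-mass distributions.
#'
#' @param d A [stratified_design()] (or design string).
#' @param p_neg,p_pos True response rates in the negative / positive stratum;
#'   may be vectors (recycled jointly for `route2`/`route3`).
#' @return Numeric vector of probabilities.
#' @examples
#' d <- parse_design("(2 1)/(34 14) -> (5/50) | (4 4)/(53 27)")
#' route1_probability(d, 0.10)              # 0.755
#' route2_probability(d, 0.03, 0.15)        # 0.1214
#' route3_probability(d, 0.03, 0.15)        # 0.5984
#' @export
route1_probability <- function(d, p_neg) {
  d <- .check_design(d)
  .check_rate(p_neg, "p_neg")
  .neg_continuation_sum(d, p_neg, binom_tail) +
    binom_tail(d$k_neg, d$N1_neg, p_neg)
}

#' @rdname route1_probability
#' @export
route2_probability <- function(d, p_neg, p_pos) {
  d <- .check_design(d)
  .check_rate(p_neg, "p_neg"); .check_rate(p_pos, "p_pos")
  binom_tail(d$k_pos, d$N_pos, p_pos) *
    .neg_continuation_sum(d, p_neg, binom_below)
}

#' @rdname route1_probability
#' @export
route3_probability <- function(d, p_neg, p_pos) {
  d <- .check_design(d)
  .check_rate(p_neg, "p_neg"); .check_rate(p_pos, "p_pos")
  hi <- min(d$N1_pos, d$ke_pos - 1)
  N2e_pos <- d$Ne_pos - d$N1_pos
  s <- rep(0, length(p_pos))
  if (hi >= d$k1_pos)
    for (i in d$k1_pos:hi)
      s <- s + binom_tail(d$ke_pos - i, N2e_pos, p_pos) *
        stats::dbinom(i, d$N1_pos, p_pos)
  binom_below(d$k1_neg, d$N1_neg, p_neg) *
    (s + binom_tail(d$ke_pos, d$N1_pos, p_pos))
}

#' Operating characteristics at one truth scenario
#'
#' Bundles the three route rejection probabilities at true rates
#' `(p_neg, p_pos)` together with the derived sums `r23 = r2 + r3` (reject
#' the positive-stratum null), `r123 = r1 + r2 + r3` (reject at least one
#' null) and `r0 = 1 - r123` (no positive outcome).
#'
#' @inheritParams route1_probability
#' @return An object of class `adaptenrich_oc`: a list with elements `r0`,
#'   `r1`, `r2`, `r3`, `r23`, `r123`, `p_neg`, `p_pos`.
#' @examples
#' d <- parse_design("(2 1)/(34 14) -> (5/50) | (4 4)/(53 27)")
#' operating_characteristics(d, 0.03, 0.03)$r123  # familywise error 0.079
#' @export
operating_characteristics <- function(d, p_neg, p_pos) {
  d <- .check_design(d)
  r1 <- route1_probability(d, p_neg)
  r2 <- route2_probability(d, p_neg, p_pos)
  r3 <- route3_probability(d, p_neg, p_pos)
  structure(list(r0 = 1 - (r1 + r2 + r3), r1 = r1, r2 = r2, r3 = r3,
                 r23 = r2 + r3, r123 = r1 + r2 + r3,
                 p_neg = p_neg, p_pos = p_pos),
            class = "adaptenrich_oc")
}

#' @export
print.adaptenrich_oc <- function(x, digits = 3, ...) {
  cat(sprintf("Operating characteristics at (p- = %g, p+ = %g)\n",
              x$p_neg, x$p_pos))
  v <- round(c(R1 = x$r1, R2 = x$r2, R3 = x$r3, R23 = x$r23,
               R123 = x$r123, R0 = x$r0), digits)
  print(v)
  invisible(x)
}

#' Outcome-by-scenario probability table
#'
#' Evaluates the design at the three canonical truth scenarios — no efficacy
#' `(p0-, p0+)`, efficacy in the unselected population `(p1-, p1-)`, and
#' efficacy in the positive stratum only `(p0-, p1+)` — and tabulates the
#' probability of each outcome (no positive result, reject both nulls,
#' reject the positive-stratum null) with its classification. A *wrong
#' positive* rejects the positive-stratum null when the effect is in the
#' unselected population, or both nulls when the effect is confined to the
#' positive stratum.
#'
#' @param d A [stratified_design()] (or design string).
#' @param h A [hypothesis_spec()].
#' @return An `outcome_table`: a 3 x 3 numeric matrix (rows: scenarios,
#'   columns: `no_positive`, `reject_both`, `reject_pos`) with a matching
#'   `"labels"` attribute classifying each cell. Rows sum to 1.
#' @examples
#' d <- parse_design("(2 1)/(34 14) -> (5/50) | (4 4)/(53 27)")
#' outcome_table(d, hypothesis_spec(0.03, 0.03, 0.10, 0.15))
#' @export
outcome_table <- function(d, h) {
  d <- .check_design(d)
  stopifnot(inherits(h, "hypothesis_spec"))
  scen <- rbind(no_efficacy = c(h$p0_neg, h$p0_pos),
                unselected = c(h$p1_neg, h$p1_neg),
                positive_only = c(h$p0_neg, h$p1_pos))
  tab <- t(apply(scen, 1, function(r) {
    oc <- operating_characteristics(d, r[1], r[2])
    c(no_positive = oc$r0, reject_both = oc$r1, reject_pos = oc$r23)
  }))
  labels <- matrix(c("true negative", "false positive", "false positive",
                     "false negative", "true positive", "wrong positive",
                     "false negative", "wrong positive", "true positive"),
                   nrow = 3, byrow = TRUE, dimnames = dimnames(tab))
  structure(tab, labels = labels, rates = scen, class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, digits = 3, ...) {
  lab <- attr(x, "labels")
  m <- matrix(sprintf("%.*f (%s)", digits, unclass(x), lab),
              nrow = nrow(x), dimnames = dimnames(x))
  cat("Outcome probabilities by truth scenario\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Overall power of a design
#'
#' The smaller of the two scenario powers: the probability of rejecting both
#' nulls when the effect is in the unselected population, `R1(p1-)`, and the
#' probability of rejecting the positive-stratum null when the effect is
#' confined to the positive stratum, `R23(p0-, p1+)`:
#' \deqn{\mathrm{power} = \min\{R_1(p_1^-),\; R_{23}(p_0^-, p_1^+)\}.}
#'
#' @inheritParams outcome_table
#' @return A single probability.
#' @examples
#' d <- parse_design("(2 1)/(34 14) -> (5/50) | (4 4)/(53 27)")
#' overall_power(d, hypothesis_spec(0.03, 0.03, 0.10, 0.15))  # 0.720
#' @export
overall_power <- function(d, h) {
  d <- .check_design(d)
  stopifnot(inherits(h, "hypothesis_spec"))
  r23 <- route2_probability(d, h$p0_neg, h$p1_pos) +
    route3_probability(d, h$p0_neg, h$p1_pos)
  min(route1_probability(d, h$p1_neg), r23)
}

#' Familywise type-I error rate
#'
#' The probability of rejecting at least one null hypothesis under the global
#' null, `R123(p0-, p0+)`. Because `R1` does not depend on the
#' positive-stratum rate, bounding this quantity also bounds the error rate
#' in the partial-null configuration, so the control extends beyond the
#' global null. [operating_characteristics()] accepts arbitrary rate pairs
#' for probing any other null configuration.
#'
#' @inheritParams outcome_table
#' @return A single probability.
#' @examples
#' d <- parse_design("(2 1)/(34 14) -> (5/50) | (4 4)/(53 27)")
#' fwer(d, hypothesis_spec(0.03, 0.03, 0.10, 0.15))  # 0.079
#' @export
fwer <- function(d, h) {
  d <- .check_design(d)
  stopifnot(inherits(h, "hypothesis_spec"))
  operating_characteristics(d, h$p0_neg, h$p0_pos)$r123
}

#' Maximise the Route-2 probability over the negative-stratum rate
#'
#' For fixed `p_pos` the Route-2 probability is not monotone in `p_neg` (low
#' negative rates make stage-1 futility likely, high rates make the
#' unselected stage 2 succeed in the negative stratum) and has a single
#' interior maximum unless the continuation region is degenerate. The
#' maximiser is located numerically: an equally spaced scan at resolution
#' `tol` followed by golden-section refinement in the bracketing interval.
#'
#' @param d A [stratified_design()] (or design string).
#' @param p_pos Fixed positive-stratum response rate.
#' @param tol Absolute tolerance on the location of the maximiser.
#' @return Named list with `p_neg` (location) and `value` (maximum). When the
#'   unselected continuation region is empty, Route 2 is identically zero and
#'   `(0, 0)` is returned.
#' @export
argmax_r2_over_pneg <- function(d, p_pos, tol = 1e-5) {
  d <- .check_design(d)
  .check_rate(p_pos, "p_pos")
  stopifnot(tol > 0)
  if (min(d$N1_neg, d$k_neg - 1) < d$k1_neg)
    return(list(p_neg = 0, value = 0))
  f <- function(p) route2_probability(d, p, p_pos)
  n_grid <- max(201L, min(20001L, ceiling(1 / tol) + 1L))
  p <- seq(0, 1, length.out = n_grid)
  vals <- f(p)
  b <- which.max(vals)
  lo <- p[max(1L, b - 1L)]; hi <- p[min(n_grid, b + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective >= vals[b])
    list(p_neg = opt$maximum, value = opt$objective)
  else
    list(p_neg = p[b], value = vals[b])
}

#' Rejection-probability curves
#'
#' Evaluates each route probability on an equally spaced grid of response
#' rates, varying one stratum's rate while holding the other fixed. Useful
#' for plotting the operating characteristics as a function of the truth, or
#' for export as CSV.
#'
#' @param d A [stratified_design()] (or design string).
#' @param vary Which rate varies along the grid: `"p_neg"` or `"p_pos"`.
#' @param fixed_rate Value at which the other rate is held.
#' @param n Number of grid points (at least 2).
#' @return A data frame with columns `p`, `R1`, `R2`, `R3`, `R123`.
#' @examples
#' d <- parse_design("(3 2)/(44 34) -> (7/104) | (9 4)/(135 53)")
#' head(rejection_curves(d, "p_neg", fixed_rate = 0.1, n = 11))
#' @export
rejection_curves <- function(d, vary = c("p_neg", "p_pos"),
                             fixed_rate = 0.03, n = 101) {
  d <- .check_design(d)
  vary <- match.arg(vary)
  .check_rate(fixed_rate, "fixed_rate")
  stopifnot(n >= 2)
  p <- seq(0, 1, length.out = n)
  if (vary == "p_neg") {
    r1 <- route1_probability(d, p)
    r2 <- route2_probability(d, p, fixed_rate)
    r3 <- route3_probability(d, p, fixed_rate)
  } else {
    r1 <- rep(route1_probability(d, fixed_rate), n)
    r2 <- route2_probability(d, fixed_rate, p)
    r3 <- route3_probability(d, fixed_rate, p)
  }
  data.frame(p = p, R1 = r1, R2 = r2, R3 = r3, R123 = r1 + r2 + r3)
}
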