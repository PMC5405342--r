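# Independent verification of the closed-form operating characteristics:
# an exact full-enumeration oracle over the joint outcome space, and a
# Monte-Carlo simulator of the trial's decision tree. Both apply the decision
# rules verbatim, without the algebraic rearrangement used by the closed
# forms, so agreement is a genuine cross-check.

.route_levels <- c("route1_reject_both", "route2_reject_pos",
                   "route3_reject_pos_enriched", "no_go_stage1_futility",
                   "no_go_stage2")

#' Exact enumeration of the trial decision tree
#'
#' Iterates over every attainable value of the stage-1 responder counts
#' `(x1-, x1+)` and, per branch, the stage-2 counts, multiplying exact
#' binomial probability masses and applying the decision rules directly:
#'
#' 1. Stage 1: early go for the unselected population if `x1- >= k_neg`
#'    (`futility_and_go` mode only); continue unselected if `x1- >= k1_neg`;
#'    otherwise examine the positive stratum — early go enriched if
#'    `x1+ >= ke_pos` (go mode only), continue enriched if `x1+ >= k1_pos`,
#'    else stop for futility.
#' 2. Unselected stage 2: reject both nulls if `x1- + x2- >= k_neg`;
#'    otherwise reject the positive-stratum null if `x1+ + x2+ >= k_pos`;
#'    else no-go.
#' 3. Enriched stage 2: reject the positive-stratum null if
#'    `x1+ + x2e+ >= ke_pos`; else no-go.
#'
#' Under `futility_only` there is no early-go branch; a stage-1 count already
#' at its cumulative threshold recruits stage 2 and is classified there (it
#' always rejects, so route probabilities agree between the modes).
#'
#' @param d A [stratified_design()] (or design string).
#' @param p_neg,p_pos True response rates.
#' @param mode Stage-1 stopping convention (see [expected_sample_size()]).
#' @param max_terms Refuse enumerations needing more than this many terms.
#' @return A list with `r0`, `r1`, `r2`, `r3`, `r23`, `r123`, `expected_n`,
#'   `pet`, `p_continue_unselected`, `p_continue_enriched` and `mode`.
#' @examples
#' d <- parse_design("(2 1)/(34 14) -> (5/50) | (4 4)/(53 27)")
#' enumerate_exact(d, 0.03, 0.15)$r23  # 0.720
#' @export
enumerate_exact <- function(d, p_neg, p_pos,
                            mode = c("futility_and_go", "futility_only"),
                            max_terms = 1e8) {
  d <- .check_design(d)
  .check_rate(p_neg, "p_neg"); .check_rate(p_pos, "p_pos")
  mode <- .match_mode(mode)
  go <- mode == "futility_and_go"
  sz <- design_sizes(d)
  n_terms <- (d$N1_neg + 1) * (d$N1_pos + 1) *
    ((sz$N2_neg + 1) * (sz$N2_pos + 1) + (sz$N2e_pos + 1))
  if (n_terms > max_terms)
    stop(sprintf("enumeration needs %.3g terms; raise max_terms to at least that",
                 n_terms), call. = FALSE)

  w1n <- stats::dbinom(0:d$N1_neg, d$N1_neg, p_neg)
  w1p <- stats::dbinom(0:d$N1_pos, d$N1_pos, p_pos)
  w2n <- stats::dbinom(0:sz$N2_neg, sz$N2_neg, p_neg)
  w2p <- stats::dbinom(0:sz$N2_pos, sz$N2_pos, p_pos)
  w2e <- stats::dbinom(0:sz$N2e_pos, sz$N2e_pos, p_pos)

  r <- c(route1 = 0, route2 = 0, route3 = 0, futility1 = 0, nogo2 = 0)
  en <- 0; pet <- 0; p_unsel <- 0; p_enr <- 0
  for (x1n in 0:d$N1_neg) {
    pn <- w1n[x1n + 1]
    if (pn == 0) next
    if (go && x1n >= d$k_neg) {
      # early go, unselected population: both nulls rejected at stage 1
      r["route1"] <- r["route1"] + pn
      en <- en + pn * sz$N1
      pet <- pet + pn
    } else if (x1n >= d$k1_neg) {
      # unselected stage 2: joint enumeration of (x2-, x2+) with x1+
      p_unsel <- p_unsel + pn
      en <- en + pn * (sz$N1 + sz$N2)
      go_n <- sum(w2n[(0:sz$N2_neg) + x1n >= d$k_neg])
      fail_n <- sum(w2n[(0:sz$N2_neg) + x1n < d$k_neg])
      r["route1"] <- r["route1"] + pn * go_n
      for (x1p in 0:d$N1_pos) {
        pp <- w1p[x1p + 1]
        if (pp == 0) next
        go_p <- sum(w2p[(0:sz$N2_pos) + x1p >= d$k_pos])
        r["route2"] <- r["route2"] + pn * pp * fail_n * go_p
        r["nogo2"] <- r["nogo2"] + pn * pp * fail_n * (1 - go_p)
      }
    } else {
      # stage-1 futility in the negative stratum: examine positives
      for (x1p in 0:d$N1_pos) {
        w <- pn * w1p[x1p + 1]
        if (w == 0) next
        if (go && x1p >= d$ke_pos) {
          r["route3"] <- r["route3"] + w
          en <- en + w * sz$N1
          pet <- pet + w
        } else if (x1p >= d$k1_pos) {
          p_enr <- p_enr + w
          en <- en + w * (sz$N1 + sz$N2e_pos)
          go_e <- sum(w2e[(0:sz$N2e_pos) + x1p >= d$ke_pos])
          r["route3"] <- r["route3"] + w * go_e
          r["nogo2"] <- r["nogo2"] + w * (1 - go_e)
        } else {
          r["futility1"] <- r["futility1"] + w
          en <- en + w * sz$N1
          pet <- pet + w
        }
      }
    }
  }
  list(r0 = unname(r["futility1"] + r["nogo2"]),
       r1 = unname(r["route1"]), r2 = unname(r["route2"]),
       r3 = unname(r["route3"]),
       r23 = unname(r["route2"] + r["route3"]),
       r123 = unname(r["route1"] + r["route2"] + r["route3"]),
       expected_n = en, pet = pet,
       p_continue_unselected = p_unsel, p_continue_enriched = p_enr,
       mode = mode)
}

#' Monte-Carlo simulation of the trial
#'
#' Draws stage-1 (and, where the trial continues, stage-2) binomial responder
#' counts and applies the same decision rules as [enumerate_exact()]. The
#' stochastic twin of the exact computations: route frequencies, mean
#' enrolment and the stage-1 stop proportion converge to the analytic values.
#'
#' @param d A [stratified_design()] (or design string).
#' @param p_neg,p_pos True response rates.
#' @param n_trials Number of simulated trials (>= 1).
#' @param seed RNG seed; identical seeds give identical output.
#' @param mode Stage-1 stopping convention.
#' @param keep_trials Also return the per-trial outcome table.
#' @return An object of class `simulation_summary`: `n_trials`,
#'   `route_frequencies` (proportions over the five terminal outcomes),
#'   `mean_enrolled`, `sd_enrolled`, `pet_hat`, `seed`, `mode`, and (when
#'   `keep_trials`) a data frame `trials` with columns `trial`, `route`,
#'   `enrolled_neg`, `enrolled_pos`, `stopped_at_stage1`.
#' @examples
#' s <- simulate_trials("(1 1)/(6 4) -> (2/9) | (3 2)/(23 5)",
#'                      0.03, 0.03, n_trials = 1000, seed = 1)
#' s$route_frequencies
#' @export
simulate_trials <- function(d, p_neg, p_pos, n_trials, seed = 1L,
                            mode = c("futility_and_go", "futility_only"),
                            keep_trials = FALSE) {
  d <- .check_design(d)
  .check_rate(p_neg, "p_neg"); .check_rate(p_pos, "p_pos")
  mode <- .match_mode(mode)
  stopifnot(n_trials >= 1)
  go <- mode == "futility_and_go"
  sz <- design_sizes(d)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  x1n <- stats::rbinom(n_trials, d$N1_neg, p_neg)
  x1p <- stats::rbinom(n_trials, d$N1_pos, p_pos)
  route <- character(n_trials)
  en_neg <- rep(d$N1_neg, n_trials)
  en_pos <- rep(d$N1_pos, n_trials)
  stage1 <- rep(TRUE, n_trials)

  early_go1 <- go & x1n >= d$k_neg
  cont_unsel <- !early_go1 & x1n >= d$k1_neg
  fut_neg <- !early_go1 & !cont_unsel
  early_go3 <- fut_neg & go & x1p >= d$ke_pos
  cont_enr <- fut_neg & !early_go3 & x1p >= d$k1_pos
  fut_stop <- fut_neg & !early_go3 & !cont_enr

  route[early_go1] <- "route1_reject_both"
  route[early_go3] <- "route3_reject_pos_enriched"
  route[fut_stop] <- "no_go_stage1_futility"

  if (any(cont_unsel)) {
    m <- sum(cont_unsel)
    x2n <- stats::rbinom(m, sz$N2_neg, p_neg)
    x2p <- stats::rbinom(m, sz$N2_pos, p_pos)
    rej_both <- x1n[cont_unsel] + x2n >= d$k_neg
    rej_pos <- !rej_both & x1p[cont_unsel] + x2p >= d$k_pos
    route[cont_unsel] <- ifelse(rej_both, "route1_reject_both",
                                ifelse(rej_pos, "route2_reject_pos", "no_go_stage2"))
    en_neg[cont_unsel] <- en_neg[cont_unsel] + sz$N2_neg
    en_pos[cont_unsel] <- en_pos[cont_unsel] + sz$N2_pos
    stage1[cont_unsel] <- FALSE
  }
  if (any(cont_enr)) {
    m <- sum(cont_enr)
    x2e <- stats::rbinom(m, sz$N2e_pos, p_pos)
    rej <- x1p[cont_enr] + x2e >= d$ke_pos
    route[cont_enr] <- ifelse(rej, "route3_reject_pos_enriched", "no_go_stage2")
    en_pos[cont_enr] <- en_pos[cont_enr] + sz$N2e_pos
    stage1[cont_enr] <- FALSE
  }

  route <- factor(route, levels = .route_levels)
  out <- structure(list(
    n_trials = n_trials,
    route_frequencies = table(route) / n_trials,
    mean_enrolled = mean(en_neg + en_pos),
    sd_enrolled = stats::sd(en_neg + en_pos),
    pet_hat = mean(stage1),
    seed = seed, mode = mode), class = "simulation_summary")
  if (keep_trials)
    out$trials <- data.frame(trial = seq_len(n_trials), route = route,
                             enrolled_neg = en_neg, enrolled_pos = en_pos,
                             stopped_at_stage1 = stage1)
  out
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("Simulated %d trials (seed %d, mode %s)\n",
              x$n_trials, x$seed, x$mode))
  print(round(x$route_frequencies, 4))
  cat(sprintf("mean enrolment %.2f (sd %.2f); stage-1 stop proportion %.4f\n",
              x$mean_enrolled, x$sd_enrolled, x$pet_hat))
  invisible(x)
}
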