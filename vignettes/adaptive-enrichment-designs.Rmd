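---
title: "Stratified adaptive-enrichment two-stage designs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified adaptive-enrichment two-stage designs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptenrich)
```

## The design

Single-arm Phase II oncology trials with a binary response endpoint
increasingly stratify participants by a dichotomous biomarker believed to be
*predictive*: biomarker-positive patients are expected to respond to the
targeted agent at least as well as biomarker-negative ones. The design family
implemented here assesses activity in both strata and adaptively *enriches*
— restricts stage-2 recruitment to biomarker-positive patients — when the
interim analysis shows no activity among biomarker-negatives.

Stage 1 recruits two parallel cohorts, $N_1^-$ biomarker-negative and
$N_1^+$ biomarker-positive participants, and counts responders $X_1^-$ and
$X_1^+$. The decision tree is:

* $X_1^- \ge k^-$ — the cumulative threshold is already met: stop and declare
  the treatment effective in the unselected population (only under the
  futility-plus-go stopping convention; see below).
* $k_1^- \le X_1^-$ (below $k^-$ in go mode) — activity among negatives:
  continue with an **unselected** cohort of $N_2 = N_2^- + N_2^+$ further
  participants. At the end, reject both nulls if $X^- = X_1^- + X_2^- \ge k^-$;
  otherwise reject only the positive-stratum null if
  $X^+ = X_1^+ + X_2^+ \ge k^+$.
* $X_1^- < k_1^-$ — negative-stratum futility: examine the positives. If
  $X_1^+ \ge k_e^+$, stop early for efficacy in the positive stratum (go mode
  only); if $k_1^+ \le X_1^+$, continue **enriched** with $N_{2e}^+$ further
  positives and reject the positive-stratum null when
  $X_e^+ = X_1^+ + X_{2e}^+ \ge k_e^+$; otherwise stop for futility.

The three positive outcomes are labelled routes: Route 1 rejects both nulls,
Route 2 rejects only $H_0^+$ after an unselected stage 2, Route 3 rejects
$H_0^+$ after enrichment. The design is indexed by ten integers, written
`(k1- k1+)/(N1- N1+) → (ke+/Ne+) | (k- k+)/(N- N+)`. All thresholds mean
"at least $k$ responders". Because responder counts within each stratum and
stage are independent binomials, every operating characteristic is an exact
finite sum — nothing in this package is asymptotic.

## Route probabilities, error and power

With $X$'s binomial at stratum rates $(p^-, p^+)$, the probabilities of the
three routes are exact conditional sums; critically, the stage-2 probability
is conditional on the stage-1 count, and the summation index runs only over
the stage-1 counts that have *not* already met the cumulative threshold:

$$R_1(p^-) = \sum_{i=k_1^-}^{\min(N_1^-, k^- - 1)}
  P(X_2^- \ge k^- - i)\,P(X_1^- = i) + P(X_1^- \ge k^-),$$

$$R_2(p^-, p^+) = P(X^+ \ge k^+)\sum_{i=k_1^-}^{\min(N_1^-, k^- - 1)}
  P(X_2^- < k^- - i)\,P(X_1^- = i),$$

$$R_3(p^-, p^+) = P(X_1^- < k_1^-)\Big[\sum_{i=k_1^+}^{\min(N_1^+, k_e^+ - 1)}
  P(X_{2e}^+ \ge k_e^+ - i)\,P(X_1^+ = i) + P(X_1^+ \ge k_e^+)\Big].$$

Two readings of the Route-3 formula are possible: the stage-1 futility
factor $P(X_1^- < k_1^-)$ could multiply only the summation or the whole
bracket. We distribute it over both terms, for a structural reason — the
positive stratum is only ever examined after stage-1 negative futility, so
the early-efficacy tail $P(X_1^+ \ge k_e^+)$ is also conditional on that
event. The distributed reading is also the one consistent with the
published operating characteristics that the test suite checks (the
undistributed reading inflates the positive-stratum power of the worked
example from 0.720 to about 0.732).

$R_1$ rises with $p^-$; $R_3$ falls with $p^-$ and rises with $p^+$; $R_2$ is
**non-monotone** in $p^-$ (a middling negative-stratum response is what makes
the unselected stage 2 run *and* fail on the negatives). Its maximiser over
$p^-$ is found numerically in `argmax_r2_over_pneg()` — grid scan then
golden-section refinement — rather than by a closed form; the stated
unimodality makes the refinement safe, and the result is verified against a
fine grid in the tests.

Error and power combine the routes:

* familywise error (weak control): $R_{123}(p_0^-, p_0^+) \le \alpha$ with
  $R_{123} = R_1 + R_2 + R_3$. Since $R_1$ is free of $p^+$, bounding the
  global null also bounds the partial-null configuration
  $(p_0^-, p^+ > p_0^+)$; `operating_characteristics()` accepts any rate
  pair so users can probe other configurations directly rather than rely on
  that argument.
* overall power: $\min\{R_1(p_1^-),\, R_{23}(p_0^-, p_1^+)\}$ — the design
  must work both when the effect is population-wide and when it is confined
  to the positive stratum.

## Expected sample size and early termination

Enrolment takes one of three values, $N_1$, $N_1 + N_2$ or
$N_1 + N_{2e}^+$, so

$$E(N) = N_1 + N_2\,P(\text{continue unselected})
  + N_{2e}^+\,P(\text{continue enriched}).$$

Two stage-1 stopping conventions are implemented, and both are first-class
because each reproduces a different part of the published reference values:

* `futility_and_go` (default): stage 1 may stop for efficacy as well as
  futility; continuation events are $k_1^- \le X_1^- < k^-$ and (after
  negative futility) $k_1^+ \le X_1^+ < k_e^+$.
* `futility_only`: the historical convention for this design family — no
  early efficacy stop; continuation events are $X_1^- \ge k_1^-$ and
  $X_1^+ \ge k_1^+$.

An early go only changes *when* the rejection is declared, never *whether*:
route probabilities are identical under the two conventions (asserted
numerically in the tests via the enumeration oracle), while $E(N)$ and the
early-termination probability differ. The early-termination probability
under the go convention is

$$PET = P(X_1^- \ge k^-) + P(X_1^- < k_1^-)\,
  [\,P(X_1^+ \ge k_e^+) + P(X_1^+ < k_1^+)\,],$$

where, as in Route 3, the negative-futility factor multiplies both
positive-stratum stop events. `expected_sample_size()` reports $E(N)$, PET
and both continuation probabilities; PET is a function of the true rates and
is conventionally reported at the global null, which is also what the
optimiser uses.

One display convention worth noting: probabilities are conventionally
reported at 3 decimals and expected sizes at 1–2 decimals, and the reference
table of futility-only expected sizes that the tests reproduce was printed
*truncated* (not rounded) at two decimals; the tests assert that truncation
identity, while all APIs return full precision.

## Numerical choices

* Binomial tails use `pbinom(..., lower.tail = FALSE)`, which sums the upper
  tail directly; the package never computes `1 - CDF` for a small tail, so
  quantities like the $5.04\times 10^{-4}$ stage-1 go probability keep full
  relative precision.
* Empty summation ranges (e.g. $k_1^- > \min(N_1^-, k^- - 1)$, a design with
  no unselected continuation region) contribute exactly 0; such designs are
  valid, and the stage-1 threshold may exceed the attainable maximum by at
  most one ($k_1 \le N_1 + 1$) — beyond that the design is rejected as
  unreachable rather than silently equivalent.
* Rates exactly 0 or 1 flow through the binomial point masses; no limiting
  arguments are needed.
* The only constraints enforced between thresholds are the structural ones
  ($k_1^- \le k^-$, $k_1^+ \le k_e^+$, each $k$ within its $N$). In
  particular $k^+ \ge k_1^+$ is *not* required: the unselected stage-2
  positive test is a separate decision from the stage-1 enrichment gate, and
  admissible optima are not excluded by an unstated rule.

## Verification strategy

`enumerate_exact()` walks the whole joint outcome space
$(x_1^-, x_1^+, x_2^-, x_2^+ \,/\, x_{2e}^+)$ applying the decision rules
verbatim and summing products of binomial masses — no algebraic
rearrangement shared with the closed forms. Agreement to $10^{-12}$ on
randomly drawn designs (all stratum sizes $\le 12$, drawn under a fixed
seed; a full sweep of that space is equivalent but slower, and the random
panel already exercises every branch including empty continuation regions)
is the package's central correctness property. `simulate_trials()` is the
stochastic twin: a seedable vectorised simulator whose route frequencies,
mean enrolment and stage-1 stop proportion are checked against the analytic
values within three standard errors.

The simulator emulates exactly what the probability model assumes: fixed
per-stratum accrual, independent binary responses at constant stratum rates,
and decisions taken exactly at the planned interim. It does not emulate
staggered accrual, response-adaptive assessment times, dropout,
misclassified biomarker status, or drift in response rates — so passing
tests validate the arithmetic of the design, not the robustness of a real
trial to those departures.

## The optimal-design search

`search_designs()` enumerates the 10-dimensional design space and returns
the feasible design (familywise error $\le \alpha$, overall power
$\ge$ the bound) minimising $E(N)$ under the global null. The enumeration is
layered so that pruning is strictly logical:

1. $(k_1^-, N_1^-, k^-, N^-)$ determine $R_1$ alone. A layer-1 tuple dies if
   $R_1(p_1^-)$ is already under-powered, or if $R_1(p_0^-)$ alone exceeds
   $\alpha$ (the other routes can only add error).
2. The six positive-stratum parameters are precomputed as a table of tail
   probabilities and continuation masses, so each surviving layer-1 tuple
   evaluates its full candidate set in vectorised arithmetic.
3. $E(N) \ge N_1$, so once an incumbent exists, layer-1 tuples whose minimum
   attainable $N_1$ exceeds the incumbent's $E(N)$ are skipped (the loop
   runs in increasing $N_1^-$, so this terminates the scan).

Candidate evaluation is pure and the incumbent update is an associative
minimum with a deterministic tie-break — smallest maximum total commitment
$N_1 + \max(N_2, N_{2e}^+)$, then smallest $N_1$, then lexicographic on the
10-tuple — so the result is independent of partitioning or evaluation order,
and repeated runs are byte-identical. `prune = FALSE` evaluates every
admissible candidate; the test suite additionally compares both against an
independent nested-loop search on a small space.

Two deliberately open choices:

* **Feasibility at reporting precision.** By default a design is feasible
  when its power *printed at three decimals* meets the bound (unrounded
  power $\ge$ bound $- 5\times10^{-4}$, error $\le \alpha + 5\times10^{-4}$).
  Reference optimal designs for this family report powers of exactly 0.800,
  which only arises under post-rounding comparison; strict unrounded
  comparison is available via `rounded_feasibility = FALSE`.
* **Bounds are mandatory.** The unconstrained space grows like the product
  of squared sample-size ranges (easily $10^{17}$ for low response rates);
  the spec object requires explicit per-parameter ranges and refuses spaces
  beyond `max_space`. The bundled catalogue
  (`optimal_design_catalogue()`) covers common target-rate settings at a 3%
  null so that large searches need not be re-run to use a known design. The
  test suite and the reproduction script run one full search — targets
  $(0.25, 0.40)$, bounds $N_1^-, N^- \le 30$, $N_1^+, N^+ \le 12$,
  $N_e^+ \le 15$, about $3.6\times10^{10}$ candidates — which completes in
  well under a minute on one CPU; the catalogue rows for low target rates
  come from much larger spaces that are not re-searched here, and are
  verified by evaluation instead (their error, power, PET and $E(N)$ are
  recomputed exactly from the design string).

No prevalence constraint ties $N_2^+/N_2$ to the biomarker prevalence:
reference optima visibly do not obey one, so imposing it would exclude them.

## Limitations

* Single-arm, binary endpoint only; no randomised comparison, no
  time-to-event endpoints, no per-patient covariates.
* Point null hypotheses: because $R_2$ (hence $R_{123}$) is non-monotone in
  $p^-$, an interval null does not inherit the error control the way it
  does for a single-stratum two-stage design. Users worried about a range
  of plausible nulls should evaluate `operating_characteristics()` across
  that range.
* The order restriction $p_1^- \le p_1^+$ is assumed, and rejection of the
  negative-stratum null entails rejecting both nulls without consulting the
  positive-stratum data; "wrong-positive" rates are reported in
  `outcome_table()` but not controlled by the optimiser.
* Expected sample size is optimised under the global null only; optimality
  under the alternative is a different criterion and is out of scope.
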