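# Route rejection probabilities, familywise error and power, checked first
# against the published operating characteristics of the worked-example
# design, then against structural properties on random designs.

test_that("worked-example design reproduces its published characteristics", {
  d <- jh_design()
  h <- jh_hypotheses()

  expect_equal(round(route1_probability(d, 0.10), 3), 0.755)
  expect_equal(round(fwer(d, h), 3), 0.079)
  oc <- operating_characteristics(d, 0.03, 0.15)
  expect_equal(round(oc$r23, 3), 0.720)
  expect_equal(round(overall_power(d, h), 3), 0.720)

  # route split at (0.03, 0.15), frozen from the full-enumeration oracle
  expect_equal(route2_probability(d, 0.03, 0.15), 0.1214019, tolerance = 1e-6)
  expect_equal(route3_probability(d, 0.03, 0.15), 0.5983881, tolerance = 1e-6)

  # remaining published power rows for the same design
  expect_equal(round(route1_probability(d, 0.03), 3), 0.067)
  expect_equal(round(route1_probability(d, 0.15), 3), 0.952)
  # the positive-stratum power column is always evaluated at p_neg = p0_neg
  expect_equal(round(operating_characteristics(d, 0.03, 0.10)$r23, 3), 0.424)
  expect_equal(round(operating_characteristics(d, 0.03, 0.25)$r23, 3), 0.905)
  expect_equal(round(operating_characteristics(d, 0.03, 0.30)$r23, 3), 0.924)
})

test_that("the stage-1 futility factor multiplies both enrichment terms", {
  # With the factor applied to both bracketed terms of the route-3 formula
  # the combined positive-stratum rejection probability prints as 0.720; the
  # alternative reading (factor on the sum only) gives about 0.732 and is
  # inconsistent with the published table.
  d <- jh_design()
  r23 <- operating_characteristics(d, 0.03, 0.15)$r23
  expect_lt(abs(r23 - 0.720), 5e-4)
  # undistributed variant: futility factor on the sum only, stage-1 tail
  # term unweighted — differs by (1 - P(X1- < k1-)) * P(X1+ >= ke+)
  futility <- pbinom(d$k1_neg - 1, d$N1_neg, 0.03)
  tail1p <- pbinom(d$ke_pos - 1, d$N1_pos, 0.15, lower.tail = FALSE)
  r23_undist <- r23 + (1 - futility) * tail1p
  expect_lt(abs(r23_undist - 0.732), 1e-3)
  expect_gt(abs(r23_undist - 0.720), 5e-3)
})

test_that("degenerate rates are handled by point-mass distributions", {
  d <- jh_design()
  expect_equal(route1_probability(d, 0), 0)      # k1_neg >= 1, no responders
  expect_equal(route1_probability(d, 1), 1)
  expect_equal(route2_probability(d, 0.5, 0), 0) # k_pos >= 1
  expect_equal(route2_probability(d, 0, 0.5), 0) # k1_neg >= 1 blocks the sum
  expect_equal(route3_probability(d, 1, 0.5), 0) # stage-1 negatives never futile
  # enrichment certain, responders certain (ke_pos reachable at stage 1)
  d2 <- stratified_design(1, 1, 6, 8, 5, 12, 3, 2, 10, 9)
  expect_equal(route3_probability(d2, 0, 1), 1)
})

test_that("probabilities over routes conserve to one", {
  set.seed(107)
  for (i in 1:300) {
    d <- random_design()
    oc <- operating_characteristics(d, runif(1), runif(1))
    expect_lt(abs(oc$r0 + oc$r1 + oc$r2 + oc$r3 - 1), 1e-12)
    expect_true(all(unlist(oc[c("r0", "r1", "r2", "r3")]) >= -1e-15))
    expect_true(all(unlist(oc[c("r0", "r1", "r2", "r3")]) <= 1 + 1e-15))
  }
})

test_that("route probabilities are monotone in the stated directions", {
  set.seed(211)
  p <- seq(0, 1, length.out = 101)
  for (i in 1:20) {
    d <- random_design()
    pp <- runif(1)
    r1 <- route1_probability(d, p)
    r3_in_pn <- route3_probability(d, p, pp)
    r2_in_pp <- route2_probability(d, pp, p)
    r3_in_pp <- route3_probability(d, pp, p)
    expect_true(all(diff(r1) >= -1e-12))       # R1 increasing in p_neg
    expect_true(all(diff(r3_in_pn) <= 1e-12))  # R3 decreasing in p_neg
    expect_true(all(diff(r2_in_pp) >= -1e-12)) # R2 increasing in p_pos
    expect_true(all(diff(r3_in_pp) >= -1e-12)) # R3 increasing in p_pos
  }
})

test_that("empty continuation regions contribute exactly zero", {
  # k1_neg = N1_neg + 1: the unselected continuation region is empty, so
  # route 1 reduces to the stage-1 tail and route 2 vanishes.
  d <- stratified_design(7, 1, 6, 4, 3, 9, 7, 2, 23, 5)
  expect_identical(route2_probability(d, 0.4, 0.4), 0)
  expect_equal(route1_probability(d, 0.4),
               pbinom(6, 6, 0.4, lower.tail = FALSE))
})

test_that("outcome table rows conserve and cells match route formulas", {
  d <- jh_design()
  h <- jh_hypotheses()
  tab <- outcome_table(d, h)
  expect_equal(unname(rowSums(unclass(tab))), rep(1, 3), tolerance = 1e-12)
  expect_equal(round(tab["no_efficacy", "reject_pos"], 3), 0.012)
  expect_equal(round(tab["no_efficacy", "reject_both"], 3), 0.067)
  expect_equal(tab["unselected", "reject_both"],
               route1_probability(d, h$p1_neg))
  expect_equal(tab["positive_only", "reject_both"],
               route1_probability(d, h$p0_neg))
  labels <- attr(tab, "labels")
  expect_equal(labels["no_efficacy", "no_positive"], "true negative")
  expect_equal(labels["unselected", "reject_pos"], "wrong positive")
  expect_equal(labels["positive_only", "reject_pos"], "true positive")
})

test_that("route-2 maximiser dominates a fine grid scan", {
  d <- jh_design()
  am <- argmax_r2_over_pneg(d, 0.15)
  grid_vals <- route2_probability(d, seq(0, 1, length.out = 201), 0.15)
  expect_gte(am$value + 1e-12, max(grid_vals))
  expect_gte(am$value, route2_probability(d, 0.03, 0.15))

  # k1_neg = 0 makes route 2 non-increasing in p_neg: boundary maximum at 0
  d0 <- stratified_design(0, 1, 6, 4, 2, 9, 3, 2, 23, 5)
  vals <- route2_probability(d0, seq(0, 1, length.out = 101), 0.4)
  expect_true(all(diff(vals) <= 1e-12))
  am0 <- argmax_r2_over_pneg(d0, 0.4)
  expect_equal(am0$value, vals[1], tolerance = 1e-6)

  # empty continuation region: route 2 identically zero
  dempty <- stratified_design(7, 1, 6, 4, 2, 9, 7, 2, 23, 5)
  expect_equal(argmax_r2_over_pneg(dempty, 0.4), list(p_neg = 0, value = 0))
})

test_that("rejection curves are well-formed and monotone where expected", {
  d <- parse_design("(3 2)/(44 34) -> (7/104) | (9 4)/(135 53)")
  tab <- rejection_curves(d, "p_neg", fixed_rate = 0.10, n = 101)
  expect_equal(nrow(tab), 101)
  expect_true(all(diff(tab$R1) >= -1e-12))
  expect_true(all(diff(tab$R3) <= 1e-12))
  expect_true(all(tab$R123 >= 0 & tab$R123 <= 1))
  tab2 <- rejection_curves(d, "p_pos", fixed_rate = 0.03, n = 51)
  expect_equal(length(unique(tab2$R1)), 1L)  # R1 free of p_pos
  expect_true(all(diff(tab2$R2) >= -1e-12))
})
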