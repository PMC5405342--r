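# Candidate evaluation and the layered, logically-pruned design search.

toy_spec <- function(...) {
  design_search_spec(hypothesis_spec(0.10, 0.10, 0.60, 0.70),
                     alpha = 0.15, power = 0.70,
                     bounds = list(N1_neg = c(1, 2), N_neg = c(1, 4),
                                   N1_pos = c(1, 2), N_pos = c(1, 3),
                                   Ne_pos = c(1, 3)),
                     max_space = 1e7, ...)
}

test_that("candidate evaluation reproduces catalogue feasibility", {
  cat <- optimal_design_catalogue()
  spec1 <- design_search_spec(
    hypothesis_spec(0.03, 0.03, 0.10, 0.10), alpha = 0.05, power = 0.80,
    bounds = list(N1_neg = c(1, 50), N_neg = c(1, 150), N1_pos = c(1, 40),
                  N_pos = c(1, 60), Ne_pos = c(1, 110)))
  ev <- evaluate_candidate(parse_design(cat$design[1]), spec1)
  expect_true(ev$feasible)
  expect_equal(round(ev$fwer, 3), 0.048)
  expect_equal(round(ev$power, 3), 0.800)
  expect_equal(round(ev$expected_n, 1), 110.2)

  # tighter error bound excludes it
  spec_tight <- design_search_spec(
    hypothesis_spec(0.03, 0.03, 0.10, 0.10), alpha = 0.04, power = 0.80,
    bounds = spec1$bounds)
  expect_false(evaluate_candidate(parse_design(cat$design[1]), spec_tight)$feasible)

  # the worked-example design is under-powered at its own targets
  spec_jh <- design_search_spec(
    hypothesis_spec(0.03, 0.03, 0.10, 0.15), alpha = 0.08, power = 0.80,
    bounds = spec1$bounds)
  ev_jh <- evaluate_candidate(jh_design(), spec_jh)
  expect_false(ev_jh$feasible)
  expect_equal(round(ev_jh$power, 3), 0.720)
})

test_that("every catalogue design is feasible under its own constraints", {
  cat <- optimal_design_catalogue()
  bounds <- list(N1_neg = c(1, 50), N_neg = c(1, 150), N1_pos = c(1, 40),
                 N_pos = c(1, 60), Ne_pos = c(1, 110))
  for (i in seq_len(nrow(cat))) {
    spec <- design_search_spec(
      hypothesis_spec(cat$p0_neg[i], cat$p0_pos[i], cat$p1_neg[i], cat$p1_pos[i]),
      alpha = 0.05, power = 0.80, bounds = bounds)
    ev <- evaluate_candidate(parse_design(cat$design[i]), spec)
    expect_true(ev$feasible, label = sprintf("feasibility of %s", cat$design[i]))
    expect_equal(round(ev$fwer, 3), cat$significance[i],
                 label = sprintf("significance of %s", cat$design[i]))
  }
})

test_that("pruned search equals the unpruned nested-loop oracle on a toy space", {
  spec <- toy_spec()
  pruned <- search_designs(spec, prune = TRUE)
  unpruned <- search_designs(spec, prune = FALSE)
  oracle <- brute_force_search(spec)
  expect_true(pruned$feasible_found)
  expect_equal(pruned$feasible_found, oracle$feasible_found)
  expect_equal(pruned$best_en, oracle$best_en, tolerance = 1e-12)
  expect_equal(unpruned$best_en, oracle$best_en, tolerance = 1e-12)
  expect_identical(format_design(pruned$best), format_design(unpruned$best))
  expect_lt(pruned$n_evaluated, unpruned$n_evaluated)
})

test_that("search results are deterministic and report a feasible best", {
  spec <- toy_spec()
  a <- search_designs(spec)
  b <- search_designs(spec)
  expect_identical(format_design(a$best), format_design(b$best))
  expect_identical(a$best_en, b$best_en)

  ev <- evaluate_candidate(a$best, spec)
  expect_true(ev$feasible)
  expect_equal(ev$expected_n, a$best_en, tolerance = 1e-12)

  # no valid one-step neighbour is feasible with strictly smaller E(N)
  fields <- names(unclass(a$best))
  for (f in fields) for (delta in c(-1L, 1L)) {
    nb <- unclass(a$best)
    nb[[f]] <- nb[[f]] + delta
    b_ok <- all(unlist(nb) >= 0) &&
      nb$N1_neg <= spec$bounds$N1_neg[2] && nb$N_neg <= spec$bounds$N_neg[2] &&
      nb$N1_pos <= spec$bounds$N1_pos[2] && nb$N_pos <= spec$bounds$N_pos[2] &&
      nb$Ne_pos <= spec$bounds$Ne_pos[2]
    if (!b_ok) next
    dn <- do.call(stratified_design, c(nb, validate = FALSE))
    if (length(validate_design(dn))) next
    evn <- evaluate_candidate(dn, spec)
    if (evn$feasible)
      expect_gte(evn$expected_n, a$best_en - 1e-12)
  }
})

test_that("restricting the bounds never decreases the best expected size", {
  spec_full <- toy_spec()
  spec_small <- design_search_spec(spec_full$hypotheses, alpha = 0.15,
                                   power = 0.70,
                                   bounds = list(N1_neg = c(1, 2), N_neg = c(1, 3),
                                                 N1_pos = c(1, 2), N_pos = c(1, 3),
                                                 Ne_pos = c(1, 2)),
                                   max_space = 1e7)
  full <- search_designs(spec_full)
  small <- search_designs(spec_small)
  expect_true(full$feasible_found)
  if (small$feasible_found)
    expect_gte(small$best_en, full$best_en - 1e-12)
})

test_that("an unattainable error bound yields no feasible design", {
  spec <- design_search_spec(hypothesis_spec(0.10, 0.10, 0.60, 0.70),
                             alpha = 1e-9, power = 0.70,
                             bounds = list(N1_neg = c(1, 2), N_neg = c(1, 3),
                                           N1_pos = c(1, 2), N_pos = c(1, 3),
                                           Ne_pos = c(1, 3)),
                             rounded_feasibility = FALSE)
  res <- search_designs(spec)
  expect_false(res$feasible_found)
  expect_true(is.na(res$best_en))
})

test_that("oversized spaces are refused with the bound sizes", {
  spec <- toy_spec()
  spec$max_space <- 10
  expect_error(search_designs(spec), "exceeding max_space")
})

test_that("search specs round-trip through YAML and JSON configs", {
  cfg <- list(hypotheses = list(p0_neg = 0.03, p0_pos = 0.03,
                                p1_neg = 0.25, p1_pos = 0.40),
              alpha = 0.05, power = 0.80,
              bounds = list(N1_neg = c(1, 30), N_neg = c(1, 30),
                            N1_pos = c(1, 12), N_pos = c(1, 12),
                            Ne_pos = c(1, 15)),
              mode = "futility_and_go", max_space = 1e11)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  spec_y <- read_search_config(yml)
  expect_s3_class(spec_y, "design_search_spec")
  expect_equal(spec_y$bounds$Ne_pos, c(1L, 15L))
  expect_equal(spec_y$hypotheses$p1_pos, 0.40)

  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE, digits = NA)
  spec_j <- read_search_config(jsn)
  expect_equal(spec_j$alpha, spec_y$alpha)
  expect_equal(spec_j$bounds, spec_y$bounds)
})
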