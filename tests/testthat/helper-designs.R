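# Shared fixtures: the worked-example design, the bundled catalogue, and a
# generator of random valid designs for property-style tests.

# Two-stage stratified design used as the running worked example (the design
# whose operating characteristics are re-derived throughout the tests).
jh_design <- function() {
  stratified_design(2, 1, 34, 14, 5, 50, 4, 4, 53, 27)
}

jh_hypotheses <- function() hypothesis_spec(0.03, 0.03, 0.10, 0.15)

catalogue_designs <- function() {
  cat <- optimal_design_catalogue()
  lapply(cat$design, parse_design)
}

# Uniformly random valid design with all sample sizes <= n_max. Thresholds
# are drawn over their full admissible ranges, including empty continuation
# regions (k1 = N1 + 1) and always-go rules (k = 0).
random_design <- function(n_max = 12) {
  rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  N1n <- rint(1, n_max); Nn <- rint(N1n, n_max)
  N1p <- rint(1, n_max); Np <- rint(N1p, n_max)
  Nep <- rint(N1p, n_max)
  kn <- rint(0, Nn); k1n <- rint(0, min(N1n + 1, kn))
  kep <- rint(0, Nep); k1p <- rint(0, min(N1p + 1, kep))
  kp <- rint(0, Np)
  stratified_design(k1n, k1p, N1n, N1p, kep, Nep, kn, kp, Nn, Np)
}

# Unpruned nested-loop search calling evaluate_candidate() on every design in
# the space: the independent oracle for pruning-soundness checks. Returns
# list(feasible_found, best_en) like a stripped-down search result.
brute_force_search <- function(spec) {
  b <- spec$bounds
  best_en <- Inf; found <- FALSE
  for (N1n in b$N1_neg[1]:b$N1_neg[2])
    for (Nn in max(N1n, b$N_neg[1]):b$N_neg[2])
      for (kn in 0:Nn) for (k1n in 0:min(N1n + 1, kn))
        for (N1p in b$N1_pos[1]:b$N1_pos[2])
          for (Np in max(N1p, b$N_pos[1]):b$N_pos[2])
            for (Nep in max(N1p, b$Ne_pos[1]):b$Ne_pos[2])
              for (kep in 0:Nep) for (k1p in 0:min(N1p + 1, kep))
                for (kp in 0:Np) {
                  d <- stratified_design(k1n, k1p, N1n, N1p, kep, Nep,
                                         kn, kp, Nn, Np)
                  ev <- evaluate_candidate(d, spec)
                  if (ev$feasible) {
                    found <- TRUE
                    if (ev$expected_n < best_en) best_en <- ev$expected_n
                  }
                }
  list(feasible_found = found,
       best_en = if (found) best_en else NA_real_)
}
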