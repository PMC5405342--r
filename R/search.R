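# Pruned exhaustive search of the 10-dimensional design space for the
# feasible design minimising expected sample size under the global null.
#
# The enumeration is layered so that every pruning step is strictly logical
# (it can never exclude a feasible design with smaller E(N)):
#
#   layer 1: (k1-, N1-, k-, N-) determine R1 alone. A tuple is pruned when
#     R1(p1-) already falls short of the power bound, or when R1(p0-) alone
#     already exceeds the error bound (R2, R3 >= 0 can only add to it).
#   layer 2: the six positive-stratum parameters complete the design; the
#     familywise error, both scenario powers and E(N) are evaluated in bulk
#     over a precomputed table of positive-stratum quantities.
#   bound: E(N) >= N1, so once a feasible design is in hand any layer-1
#     tuple whose minimum attainable N1 exceeds the incumbent E(N) is skipped.
#
# Candidate evaluation is pure and the incumbent update is an associative
# min with a deterministic tie-break, so partitioning or reordering the
# space cannot change the result.

#' Specify a design search
#'
#' @param hypotheses A [hypothesis_spec()].
#' @param alpha Familywise type-I error bound (e.g. 0.05).
#' @param power Lower bound on the overall power of [overall_power()].
#' @param bounds Named list of inclusive integer ranges `c(lower, upper)` for
#'   the five sample-size parameters `N1_neg`, `N_neg`, `N1_pos`, `N_pos`,
#'   `Ne_pos`. Threshold ranges are derived (0 up to the relevant size, plus
#'   the empty-continuation value `N1 + 1` for stage-1 thresholds). Explicit
#'   upper bounds are required: the space grows like the product of the
#'   squared ranges and an unbounded run is refused.
#' @param mode Stopping convention used for the E(N) objective
#'   (default `"futility_and_go"`).
#' @param max_space Refuse searches whose candidate space exceeds this many
#'   designs.
#' @param rounded_feasibility If `TRUE` (default), feasibility is judged at
#'   3-decimal reporting precision: unrounded power `>= power - 5e-4` and
#'   unrounded error `<= alpha + 5e-4`, i.e. a design whose power *prints* as
#'   meeting the bound is admitted. Set `FALSE` for strict unrounded
#'   comparison.
#' @return An object of class `design_search_spec`.
#' @examples
#' design_search_spec(hypothesis_spec(0.03, 0.03, 0.25, 0.40),
#'                    alpha = 0.05, power = 0.80,
#'                    bounds = list(N1_neg = c(1, 30), N_neg = c(1, 30),
#'                                  N1_pos = c(1, 12), N_pos = c(1, 12),
#'                                  Ne_pos = c(1, 15)))
#' @export
design_search_spec <- function(hypotheses, alpha = 0.05, power = 0.80, bounds,
                               mode = c("futility_and_go", "futility_only"),
                               max_space = 1e8, rounded_feasibility = TRUE) {
  stopifnot(inherits(hypotheses, "hypothesis_spec"),
            alpha > 0, alpha < 1, power > 0, power < 1, max_space > 0)
  mode <- .match_mode(mode)
  need <- c("N1_neg", "N_neg", "N1_pos", "N_pos", "Ne_pos")
  miss <- setdiff(need, names(bounds))
  if (length(miss))
    stop("bounds must give ranges for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in need) {
    b <- bounds[[nm]]
    if (length(b) != 2 || any(b < 0) || b[1] > b[2] || any(b != floor(b)))
      stop("bounds$", nm, " must be an integer range c(lower, upper)",
           call. = FALSE)
    bounds[[nm]] <- as.integer(b)
  }
  structure(list(hypotheses = hypotheses, alpha = alpha, power = power,
                 bounds = bounds[need], mode = mode, max_space = max_space,
                 rounded_feasibility = rounded_feasibility),
            class = "design_search_spec")
}

.thresholds <- function(spec) {
  slack <- if (spec$rounded_feasibility) 5e-4 else 0
  list(alpha = spec$alpha + slack, power = spec$power - slack)
}

#' Evaluate one candidate design against search constraints
#'
#' @param d A [stratified_design()] (or design string).
#' @param spec A [design_search_spec()].
#' @return List with `feasible` (error and power constraints met under the
#'   spec's comparison convention), `fwer`, `power` and `expected_n` (at the
#'   global null, under the spec's stopping mode).
#' @examples
#' spec <- design_search_spec(hypothesis_spec(0.03, 0.03, 0.10, 0.10),
#'                            bounds = list(N1_neg = c(1, 50), N_neg = c(1, 150),
#'                                          N1_pos = c(1, 40), N_pos = c(1, 60),
#'                                          Ne_pos = c(1, 110)))
#' evaluate_candidate("(3 2)/(44 34) -> (7/104) | (9 4)/(135 53)", spec)
#' @export
evaluate_candidate <- function(d, spec) {
  d <- .check_design(d)
  stopifnot(inherits(spec, "design_search_spec"))
  h <- spec$hypotheses
  thr <- .thresholds(spec)
  fw <- fwer(d, h)
  pw <- overall_power(d, h)
  en <- expected_sample_size(d, h$p0_neg, h$p0_pos, mode = spec$mode)$expected_n
  list(feasible = fw <= thr$alpha && pw >= thr$power,
       fwer = fw, power = pw, expected_n = en)
}

# Layer-1 table: every admissible (N1-, N-, k1-, k-) with the quantities the
# later layers need, all under the spec's rates. Columns:
#   R1_0, R1_1  route-1 probability at p0- and p1-
#   S0          stage-2 negative-failure sum at p0- (the route-2 factor)
#   A0          P(X1- < k1-) at p0-
#   Pc0         stage-1 unselected continuation probability at p0- (per mode)
.layer1_table <- function(spec) {
  h <- spec$hypotheses; b <- spec$bounds
  go <- spec$mode == "futility_and_go"
  acc <- vector("list", 1024); n_acc <- 0
  for (N1n in b$N1_neg[1]:b$N1_neg[2]) {
    db0 <- stats::dbinom(0:N1n, N1n, h$p0_neg)
    db1 <- stats::dbinom(0:N1n, N1n, h$p1_neg)
    F0 <- cumsum(db0)                       # F0[i+1] = P(X1- <= i)
    F1 <- cumsum(db1)
    for (Nn in max(N1n, b$N_neg[1]):b$N_neg[2]) {
      N2n <- Nn - N1n
      # tail2*[j+1] = P(X2- >= j), below2*[j+1] = P(X2- < j), j = 0..N2n+1
      tail20 <- c(1, stats::pbinom(0:N2n, N2n, h$p0_neg, lower.tail = FALSE))
      tail21 <- c(1, stats::pbinom(0:N2n, N2n, h$p1_neg, lower.tail = FALSE))
      for (kn in 0:Nn) {
        k1_max <- min(N1n + 1, kn)
        k1 <- 0:k1_max
        hi <- min(N1n, kn - 1)
        if (hi >= 0) {
          i <- 0:hi
          j <- pmin(kn - i, N2n + 1)        # P(X2- >= j) = 0 beyond N2n
          t0 <- tail20[j + 1] * db0[i + 1]
          t1 <- tail21[j + 1] * db1[i + 1]
          f0 <- (1 - tail20[j + 1]) * db0[i + 1]
          # reverse cumulative sums: sum over i >= k1
          rs <- function(v, k1v) {
            cs <- rev(cumsum(rev(v)))       # cs[i+1] = sum_{l >= i} v
            out <- rep(0, length(k1v))
            ok <- k1v <= hi
            out[ok] <- cs[k1v[ok] + 1]
            out
          }
          sum0 <- rs(t0, k1); sum1 <- rs(t1, k1); S0 <- rs(f0, k1)
        } else {
          sum0 <- sum1 <- S0 <- rep(0, length(k1))
        }
        tail1_0 <- if (kn <= 0) 1 else
          stats::pbinom(kn - 1, N1n, h$p0_neg, lower.tail = FALSE)
        tail1_1 <- if (kn <= 0) 1 else
          stats::pbinom(kn - 1, N1n, h$p1_neg, lower.tail = FALSE)
        A0 <- c(0, F0)[k1 + 1]              # P(X1- < k1)
        Pc0 <- if (go) {
          below_kn <- if (kn <= 0) 0 else if (kn > N1n) 1 else F0[kn]
          below_kn - A0
        } else 1 - A0
        n_acc <- n_acc + 1
        if (n_acc > length(acc)) acc <- c(acc, vector("list", length(acc)))
        acc[[n_acc]] <- data.frame(N1n = N1n, Nn = Nn, k1n = k1, kn = kn,
                                   R1_0 = sum0 + tail1_0, R1_1 = sum1 + tail1_1,
                                   S0 = S0, A0 = A0, Pc0 = Pc0)
      }
    }
  }
  do.call(rbind, acc[seq_len(n_acc)])
}

# Positive-stratum candidate table: every admissible
# (N1+, k1+, Ne+, ke+, N+, k+) with
#   G0, G1   the route-3 bracket at p0+ and p1+
#   T0, T1   P(X+ >= k+) at p0+ and p1+
#   Pe0      stage-1 enriched continuation probability at p0+ (per mode)
.positive_table <- function(spec) {
  h <- spec$hypotheses; b <- spec$bounds
  go <- spec$mode == "futility_and_go"
  accA <- list(); nA <- 0
  for (N1p in b$N1_pos[1]:b$N1_pos[2]) {
    db0 <- stats::dbinom(0:N1p, N1p, h$p0_pos)
    db1 <- stats::dbinom(0:N1p, N1p, h$p1_pos)
    F0 <- cumsum(db0)
    if (N1p > b$Ne_pos[2]) next
    for (Nep in max(N1p, b$Ne_pos[1]):b$Ne_pos[2]) {
      N2e <- Nep - N1p
      tail0 <- c(1, stats::pbinom(0:N2e, N2e, h$p0_pos, lower.tail = FALSE))
      tail1 <- c(1, stats::pbinom(0:N2e, N2e, h$p1_pos, lower.tail = FALSE))
      for (kep in 0:Nep) {
        k1_max <- min(N1p + 1, kep)
        k1 <- 0:k1_max
        hi <- min(N1p, kep - 1)
        if (hi >= 0) {
          i <- 0:hi
          j <- pmin(kep - i, N2e + 1)
          t0 <- tail0[j + 1] * db0[i + 1]
          t1 <- tail1[j + 1] * db1[i + 1]
          cs0 <- rev(cumsum(rev(t0))); cs1 <- rev(cumsum(rev(t1)))
          g0 <- g1 <- rep(0, length(k1))
          ok <- k1 <= hi
          g0[ok] <- cs0[k1[ok] + 1]; g1[ok] <- cs1[k1[ok] + 1]
        } else g0 <- g1 <- rep(0, length(k1))
        t1p_0 <- if (kep <= 0) 1 else
          stats::pbinom(kep - 1, N1p, h$p0_pos, lower.tail = FALSE)
        t1p_1 <- if (kep <= 0) 1 else
          stats::pbinom(kep - 1, N1p, h$p1_pos, lower.tail = FALSE)
        A0p <- c(0, F0)[k1 + 1]
        Pe0 <- if (go) {
          below_ke <- if (kep <= 0) 0 else if (kep > N1p) 1 else F0[kep]
          below_ke - A0p
        } else 1 - A0p
        nA <- nA + 1
        accA[[nA]] <- data.frame(N1p = N1p, k1p = k1, Nep = Nep, kep = kep,
                                 G0 = g0 + t1p_0, G1 = g1 + t1p_1, Pe0 = Pe0)
      }
    }
  }
  A <- do.call(rbind, accA)
  accB <- list(); nB <- 0
  for (N1p in b$N1_pos[1]:b$N1_pos[2]) {
    if (N1p > b$N_pos[2]) next
    for (Np in max(N1p, b$N_pos[1]):b$N_pos[2]) {
      kp <- 0:Np
      nB <- nB + 1
      accB[[nB]] <- data.frame(
        N1p = N1p, Np = Np, kp = kp,
        T0 = c(1, stats::pbinom(0:(Np - 1), Np, spec$hypotheses$p0_pos,
                                lower.tail = FALSE))[kp + 1],
        T1 = c(1, stats::pbinom(0:(Np - 1), Np, spec$hypotheses$p1_pos,
                                lower.tail = FALSE))[kp + 1])
    }
  }
  B <- do.call(rbind, accB)
  merge(A, B, by = "N1p")
}

.candidate_key <- function(en, tb1, tb2, d) {
  c(en, tb1, tb2, d$k1_neg, d$k1_pos, d$N1_neg, d$N1_pos,
    d$ke_pos, d$Ne_pos, d$k_neg, d$k_pos, d$N_neg, d$N_pos)
}

.key_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Search the design space for the minimum-E(N) design
#'
#' Enumerates every design within the spec's bounds, keeps those meeting the
#' familywise error and power constraints, and returns the one with the
#' smallest expected sample size under the global null. See the file-level
#' notes for the layered pruning scheme; with `prune = FALSE` every admissible
#' candidate is evaluated (useful for verifying pruning soundness on small
#' spaces).
#'
#' Ties in E(N) are broken deterministically: smallest maximum total
#' commitment `N1 + max(N2, N2e+)`, then smallest `N1`, then lexicographically
#' on the 10-tuple `(k1-, k1+, N1-, N1+, ke+, Ne+, k-, k+, N-, N+)`.
#'
#' @param spec A [design_search_spec()].
#' @param prune Apply the logical pruning rules (default `TRUE`).
#' @param verbose Print progress to stderr.
#' @return An object of class `design_search_result`: `feasible_found`,
#'   `best` (a [stratified_design()] or `NULL`), `best_en`, `best_fwer`,
#'   `best_power`, `best_oc` (operating characteristics at the null and the
#'   two power scenarios), `n_evaluated`, `n_pruned`, `n_space`, `spec`.
#' @export
search_designs <- function(spec, prune = TRUE, verbose = FALSE) {
  stopifnot(inherits(spec, "design_search_spec"))
  thr <- .thresholds(spec)
  L1 <- .layer1_table(spec)
  pos <- .positive_table(spec)
  n_space <- as.double(nrow(L1)) * nrow(pos)
  if (n_space > spec$max_space)
    stop(sprintf(paste0("design space has %.3g candidates ",
                        "(%d negative-stratum x %d positive-stratum tuples), ",
                        "exceeding max_space = %.3g"),
                 n_space, nrow(L1), nrow(pos), spec$max_space), call. = FALSE)
  if (verbose)
    message(sprintf("search space: %d x %d = %.3g candidates",
                    nrow(L1), nrow(pos), n_space))

  n_pruned <- 0; n_evaluated <- 0
  if (prune) {
    keep <- L1$R1_1 >= thr$power & L1$R1_0 <= thr$alpha
    n_pruned <- n_pruned + sum(!keep) * as.double(nrow(pos))
    L1 <- L1[keep, , drop = FALSE]
  }
  L1 <- L1[order(L1$N1n, L1$Nn, L1$kn, L1$k1n), , drop = FALSE]

  min_N1p <- min(pos$N1p)
  N2e <- pos$Nep - pos$N1p
  N2p <- pos$Np - pos$N1p
  pos_tb_neg <- NULL  # per-row positive part of tie-break, filled lazily

  best_key <- NULL; best_row <- NULL; best_l1 <- NULL
  best_en <- Inf
  for (r in seq_len(nrow(L1))) {
    N1n <- L1$N1n[r]; N2n <- L1$Nn[r] - N1n
    if (prune && N1n + min_N1p > best_en) {
      n_pruned <- n_pruned + (nrow(L1) - r + 1) * as.double(nrow(pos))
      break  # L1 sorted by N1n: all later tuples are at least as large
    }
    en <- (N1n + pos$N1p) + (N2n + N2p) * L1$Pc0[r] +
      N2e * L1$A0[r] * pos$Pe0
    fw <- L1$R1_0[r] + L1$S0[r] * pos$T0 + L1$A0[r] * pos$G0
    pw <- pmin(L1$R1_1[r], L1$S0[r] * pos$T1 + L1$A0[r] * pos$G1)
    n_evaluated <- n_evaluated + nrow(pos)
    idx <- which(fw <= thr$alpha & pw >= thr$power & en <= best_en)
    if (!length(idx)) next
    tb1 <- (N1n + pos$N1p[idx]) + pmax(N2n + N2p[idx], N2e[idx])
    tb2 <- N1n + pos$N1p[idx]
    ord <- order(en[idx], tb1, tb2, pos$k1p[idx], pos$N1p[idx],
                 pos$kep[idx], pos$Nep[idx], pos$kp[idx], pos$Np[idx])
    i <- idx[ord[1]]
    d <- stratified_design(L1$k1n[r], pos$k1p[i], N1n, pos$N1p[i],
                           pos$kep[i], pos$Nep[i], L1$kn[r], pos$kp[i],
                           L1$Nn[r], pos$Np[i])
    key <- .candidate_key(en[i],
                          (N1n + pos$N1p[i]) + max(N2n + N2p[i], N2e[i]),
                          N1n + pos$N1p[i], d)
    if (is.null(best_key) || .key_less(key, best_key)) {
      best_key <- key; best_row <- d; best_en <- en[i]
      if (verbose)
        message(sprintf("incumbent: E(N) = %.4f  %s", en[i], format_design(d)))
    }
  }

  h <- spec$hypotheses
  res <- list(feasible_found = !is.null(best_row), best = best_row,
              best_en = if (is.null(best_row)) NA_real_ else best_en,
              best_fwer = NA_real_, best_power = NA_real_, best_oc = NULL,
              n_evaluated = n_evaluated, n_pruned = n_pruned,
              n_space = n_space, spec = spec)
  if (!is.null(best_row)) {
    res$best_fwer <- fwer(best_row, h)
    res$best_power <- overall_power(best_row, h)
    res$best_oc <- list(
      null = operating_characteristics(best_row, h$p0_neg, h$p0_pos),
      unselected = operating_characteristics(best_row, h$p1_neg, h$p1_neg),
      positive_only = operating_characteristics(best_row, h$p0_neg, h$p1_pos))
  }
  structure(res, class = "design_search_result")
}

#' @export
print.design_search_result <- function(x, ...) {
  cat("Design search result\n")
  cat(sprintf("  space: %.4g candidates; evaluated %.4g, pruned %.4g\n",
              x$n_space, x$n_evaluated, x$n_pruned))
  if (x$feasible_found) {
    cat("  best:", format_design(x$best), "\n")
    cat(sprintf("  E(N) = %.2f at the global null; FWER = %.3f; power = %.3f\n",
                x$best_en, x$best_fwer, x$best_power))
  } else {
    cat("  no feasible design in the searched space\n")
  }
  invisible(x)
}

#' Read a search specification from a YAML or JSON config file
#'
#' The file mirrors [design_search_spec()]: keys `hypotheses` (with `p0_neg`,
#' `p0_pos`, `p1_neg`, `p1_pos`), `alpha`, `power`, `bounds` (each a 2-vector),
#' and optionally `mode`, `max_space`, `rounded_feasibility`.
#'
#' @param path Config file path; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return A [design_search_spec()].
#' @export
read_search_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  hy <- cfg$hypotheses
  if (is.null(hy)) stop("config is missing the 'hypotheses' block", call. = FALSE)
  spec <- design_search_spec(
    hypotheses = hypothesis_spec(hy$p0_neg, hy$p0_pos, hy$p1_neg, hy$p1_pos),
    alpha = cfg$alpha %||% 0.05,
    power = cfg$power %||% 0.80,
    bounds = lapply(cfg$bounds, as.numeric),
    mode = cfg$mode %||% "futility_and_go",
    max_space = cfg$max_space %||% 1e8,
    rounded_feasibility = cfg$rounded_feasibility %||% TRUE)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
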