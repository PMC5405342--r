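# Full evaluation report for one design, the bundled design catalogue, and
# tabular/JSON serialisation helpers used by the command-line interface.

#' Full evaluation report for a design
#'
#' Computes everything the package knows about one design under one
#' hypothesis setting: route probabilities at the three truth scenarios, the
#' outcome classification table, overall power, familywise error, expected
#' sample size under both stopping conventions and the early-termination
#' probability (both at the global null).
#'
#' @param d A [stratified_design()] (or design string).
#' @param h A [hypothesis_spec()].
#' @return An object of class `evaluation_report`: a list with `design`,
#'   `design_string`, `hypotheses`, `scenarios` (a data frame of route
#'   probabilities per scenario), `outcomes` (the [outcome_table()]),
#'   `power`, `fwer`, `en_futility_and_go`, `en_futility_only`, `pet`.
#' @examples
#' report <- evaluate_design("(2 1)/(34 14) -> (5/50) | (4 4)/(53 27)",
#'                           hypothesis_spec(0.03, 0.03, 0.10, 0.15))
#' report
#' @export
evaluate_design <- function(d, h) {
  d <- .check_design(d)
  stopifnot(inherits(h, "hypothesis_spec"))
  scen <- rbind(no_efficacy = c(h$p0_neg, h$p0_pos),
                unselected = c(h$p1_neg, h$p1_neg),
                positive_only = c(h$p0_neg, h$p1_pos))
  rows <- lapply(rownames(scen), function(s) {
    oc <- operating_characteristics(d, scen[s, 1], scen[s, 2])
    data.frame(scenario = s, p_neg = scen[s, 1], p_pos = scen[s, 2],
               R1 = oc$r1, R2 = oc$r2, R3 = oc$r3,
               R23 = oc$r23, R123 = oc$r123, R0 = oc$r0)
  })
  en_go <- expected_sample_size(d, h$p0_neg, h$p0_pos, "futility_and_go")
  en_fo <- expected_sample_size(d, h$p0_neg, h$p0_pos, "futility_only")
  structure(list(design = d, design_string = format_design(d),
                 hypotheses = h,
                 scenarios = do.call(rbind, rows),
                 outcomes = outcome_table(d, h),
                 power = overall_power(d, h), fwer = fwer(d, h),
                 en_futility_and_go = en_go$expected_n,
                 en_futility_only = en_fo$expected_n,
                 pet = early_termination_probability(d, h$p0_neg, h$p0_pos)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("Design evaluation\n ", x$design_string, "\n")
  print(x$hypotheses)
  s <- x$scenarios
  s[, 4:9] <- round(s[, 4:9], digits)
  print(s, row.names = FALSE)
  cat(sprintf("overall power = %.3f; familywise error = %.3f\n",
              x$power, x$fwer))
  cat(sprintf("at the global null: E(N) = %.2f (futility+go) / %.2f (futility only); PET = %.3f\n",
              x$en_futility_and_go, x$en_futility_only, x$pet))
  invisible(x)
}

#' Flatten an evaluation report to one data-frame row per scenario
#'
#' Full-precision values; suitable for CSV export.
#' @param report An [evaluate_design()] result.
#' @return A data frame.
#' @export
report_as_table <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  s <- report$scenarios
  cbind(design = report$design_string, s,
        power = report$power, fwer = report$fwer,
        EN_with_go_stop = report$en_futility_and_go,
        EN_futility_only = report$en_futility_only,
        PET = report$pet)
}

#' Serialise an evaluation report as JSON
#'
#' @param report An [evaluate_design()] result.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_as_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(design = report$design_string,
              parameters = unclass(report$design),
              hypotheses = unclass(report$hypotheses),
              scenarios = report$scenarios,
              outcome_probabilities = unclass(report$outcomes)[, ],
              outcome_labels = attr(report$outcomes, "labels"),
              power = report$power, fwer = report$fwer,
              EN_with_go_stop = report$en_futility_and_go,
              EN_futility_only = report$en_futility_only,
              PET = report$pet)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Bundled catalogue of optimal designs
#'
#' Reference minimum-E(N) designs for a 3% null response rate in both strata,
#' controlling the familywise error at 5% with at least 80% power, at a range
#' of target response rates. Each row records the target rates, the design
#' string and its nominal operating characteristics (significance, the two
#' scenario powers, early-termination probability and expected sample size at
#' the global null under futility-plus-efficacy stopping) — all of which the
#' package recomputes exactly from the design string.
#'
#' @return A data frame with columns `p0_neg`, `p0_pos`, `p1_neg`, `p1_pos`,
#'   `significance`, `power_unselected`, `power_positive`, `pet`,
#'   `expected_n`, `design`.
#' @examples
#' cat <- optimal_design_catalogue()
#' fwer(parse_design(cat$design[1]),
#'      hypothesis_spec(0.03, 0.03, cat$p1_neg[1], cat$p1_pos[1]))
#' @export
optimal_design_catalogue <- function() {
  path <- system.file("extdata", "optimal_design_catalogue.csv",
                      package = "adaptenrich", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
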