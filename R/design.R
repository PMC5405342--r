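#' Construct a stratified adaptive-enrichment two-stage design
#'
#' A design for a single-arm Phase II trial with a binary endpoint and two
#' biomarker strata (negative / positive). Stage 1 recruits both strata in
#' parallel; depending on the stage-1 responder counts the trial either stops,
#' continues with an unselected cohort, or continues with a biomarker-positive
#' (enriched) cohort. The design is indexed completely by ten integers,
#' conventionally written
#' `"(k1- k1+)/(N1- N1+) -> (ke+/Ne+) | (k- k+)/(N- N+)"`.
#'
#' Thresholds are always "at least k responders": a stratum passes a gate when
#' its (cumulative) responder count is greater than or equal to the threshold.
#'
#' @param k1_neg Stage-1 continuation threshold, biomarker-negative stratum.
#' @param k1_pos Stage-1 continuation threshold, biomarker-positive stratum
#'   (only examined after stage-1 negative futility).
#' @param N1_neg,N1_pos Stage-1 sample sizes per stratum.
#' @param ke_pos Cumulative responder threshold in the positive stratum after
#'   an enriched stage 2.
#' @param Ne_pos Cumulative positive-stratum sample size under enrichment.
#' @param k_neg,k_pos Cumulative responder thresholds after an unselected
#'   stage 2.
#' @param N_neg,N_pos Cumulative per-stratum sample sizes after an unselected
#'   stage 2.
#' @param validate If `TRUE` (default), reject invalid parameter combinations.
#'
#' @return An object of class `stratified_design`: a named list of the ten
#'   integer parameters. Derived sizes are available via [design_sizes()].
#'
#' @details A continuation threshold equal to the attainable maximum plus one
#'   (`k1_neg = N1_neg + 1`) is allowed and makes the corresponding
#'   continuation region empty; larger values are rejected as unreachable.
#'
#' @examples
#' d <- stratified_design(2, 1, 34, 14, 5, 50, 4, 4, 53, 27)
#' format_design(d)
#' design_sizes(d)
#' @seealso [parse_design()], [format_design()], [validate_design()]
#' @export
stratified_design <- function(k1_neg, k1_pos, N1_neg, N1_pos,
                              ke_pos, Ne_pos, k_neg, k_pos, N_neg, N_pos,
                              validate = TRUE) {
  d <- structure(
    list(k1_neg = as.integer(k1_neg), k1_pos = as.integer(k1_pos),
         N1_neg = as.integer(N1_neg), N1_pos = as.integer(N1_pos),
         ke_pos = as.integer(ke_pos), Ne_pos = as.integer(Ne_pos),
         k_neg = as.integer(k_neg), k_pos = as.integer(k_pos),
         N_neg = as.integer(N_neg), N_pos = as.integer(N_pos)),
    class = "stratified_design")
  if (validate) {
    v <- validate_design(d)
    if (length(v))
      stop("invalid stratified design:\n  ", paste(v, collapse = "\n  "),
           call. = FALSE)
  }
  d
}

#' Derived sample sizes of a design
#'
#' @param d A [stratified_design()].
#' @return Named list with `N1` (total stage-1 size), `N2_neg`, `N2_pos`
#'   (per-stratum unselected stage-2 sizes), `N2` (their sum) and `N2e_pos`
#'   (enriched stage-2 size).
#' @export
design_sizes <- function(d) {
  stopifnot(inherits(d, "stratified_design"))
  list(N1 = d$N1_neg + d$N1_pos,
       N2_neg = d$N_neg - d$N1_neg,
       N2_pos = d$N_pos - d$N1_pos,
       N2 = (d$N_neg - d$N1_neg) + (d$N_pos - d$N1_pos),
       N2e_pos = d$Ne_pos - d$N1_pos)
}

#' Validate a stratified design
#'
#' Checks every structural invariant of the design and returns a description
#' of each violation instead of raising an error, so that search and I/O code
#' can report all problems at once.
#'
#' @param d A `stratified_design` (or a bare named list with the ten fields).
#' @return Character vector of violation descriptions; empty when valid.
#' @examples
#' d <- stratified_design(5, 1, 10, 5, 3, 8, 4, 2, 12, 6, validate = FALSE)
#' validate_design(d)  # k1_neg exceeds k_neg
#' @export
validate_design <- function(d) {
  fields <- c("k1_neg", "k1_pos", "N1_neg", "N1_pos", "ke_pos", "Ne_pos",
              "k_neg", "k_pos", "N_neg", "N_pos")
  miss <- setdiff(fields, names(d))
  if (length(miss))
    return(paste0("missing field(s): ", paste(miss, collapse = ", ")))
  v <- character(0)
  vals <- unlist(d[fields])
  bad <- fields[is.na(vals) | vals < 0 | vals != floor(vals)]
  if (length(bad))
    v <- c(v, paste0(paste(bad, collapse = ", "),
                     ": all parameters must be non-negative integers"))
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(d$k1_neg <= d$k_neg, "k1_neg must not exceed k_neg")
  chk(d$k1_pos <= d$ke_pos, "k1_pos must not exceed ke_pos")
  chk(d$N1_neg <= d$N_neg, "N1_neg must not exceed N_neg")
  chk(d$N1_pos <= d$N_pos, "N1_pos must not exceed N_pos")
  chk(d$N1_pos <= d$Ne_pos, "N1_pos must not exceed Ne_pos")
  chk(d$k_neg <= d$N_neg, "k_neg must not exceed N_neg")
  chk(d$k_pos <= d$N_pos, "k_pos must not exceed N_pos")
  chk(d$ke_pos <= d$Ne_pos, "ke_pos must not exceed Ne_pos")
  chk(d$k1_neg <= d$N1_neg + 1, "k1_neg exceeds N1_neg + 1 (unreachable)")
  chk(d$k1_pos <= d$N1_pos + 1, "k1_pos exceeds N1_pos + 1 (unreachable)")
  v
}

# canonical skeleton of a design string once digits and blanks are removed
.design_skeleton <- "()/()->(/)|()/()"

#' Parse a design string
#'
#' Reads the compact ten-parameter notation
#' `"(k1- k1+)/(N1- N1+) -> (ke+/Ne+) | (k- k+)/(N- N+)"`. Both the Unicode
#' arrow `"→"` and ASCII `"->"` are accepted; whitespace is flexible.
#'
#' @param text A single design string.
#' @param validate Check design invariants after parsing (default `TRUE`).
#' @return A [stratified_design()].
#' @examples
#' parse_design("(3 2)/(44 34) -> (7/104) | (9 4)/(135 53)")
#' @export
parse_design <- function(text, validate = TRUE) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("→", "->", text, fixed = TRUE)
  skel <- gsub("[0-9[:space:]]", "", s)
  if (skel != .design_skeleton) {
    exp <- strsplit(.design_skeleton, "")[[1]]
    got <- strsplit(skel, "")[[1]]
    n <- min(length(exp), length(got))
    pos <- which(exp[seq_len(n)] != got[seq_len(n)])
    pos <- if (length(pos)) pos[1] else n + 1L
    stop(sprintf(paste0("cannot parse design string: expected '%s' at ",
                        "punctuation token %d, got '%s' in \"%s\""),
                 if (pos <= length(exp)) exp[pos] else "<end>", pos,
                 if (pos <= length(got)) got[pos] else "<end>", text),
         call. = FALSE)
  }
  tok <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
  if (length(tok) != 10L)
    stop(sprintf("cannot parse design string: expected 10 integers, found %d",
                 length(tok)), call. = FALSE)
  n <- as.integer(tok)
  stratified_design(n[1], n[2], n[3], n[4], n[5], n[6], n[7], n[8], n[9], n[10],
                    validate = validate)
}

#' Format a design as its canonical string
#'
#' @param d A [stratified_design()].
#' @param ascii Use `"->"` instead of the Unicode arrow (default `FALSE`).
#' @return The canonical design string; [parse_design()] round-trips it.
#' @export
format_design <- function(d, ascii = FALSE) {
  stopifnot(inherits(d, "stratified_design"))
  arrow <- if (ascii) "->" else "→"
  sprintf("(%d %d)/(%d %d) %s (%d/%d) | (%d %d)/(%d %d)",
          d$k1_neg, d$k1_pos, d$N1_neg, d$N1_pos, arrow,
          d$ke_pos, d$Ne_pos, d$k_neg, d$k_pos, d$N_neg, d$N_pos)
}

#' @export
format.stratified_design <- function(x, ...) format_design(x)

#' @export
print.stratified_design <- function(x, ...) {
  sz <- design_sizes(x)
  cat("Stratified adaptive-enrichment two-stage design\n")
  cat(" ", format_design(x), "\n")
  cat(sprintf("  stage 1: %d (%d neg + %d pos); unselected stage 2: +%d; enriched stage 2: +%d\n",
              sz$N1, x$N1_neg, x$N1_pos, sz$N2, sz$N2e_pos))
  invisible(x)
}

#' @export
as.data.frame.stratified_design <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Hypothesis rates for the two strata
#'
#' Null and target response rates defining the testing problem. The strata
#' share a testing family: `H0-: p- = p0_neg` and `H0+: p+ = p0_pos`, with
#' targets `p1_neg`, `p1_pos`. The biomarker is assumed predictive, so the
#' target rates are order-restricted (`p1_neg <= p1_pos`); the nulls are
#' usually equal (no prognostic effect) but may differ.
#'
#' @param p0_neg,p0_pos Null response rates per stratum.
#' @param p1_neg,p1_pos Target (alternative) response rates per stratum;
#'   must exceed the corresponding null.
#' @return An object of class `hypothesis_spec`.
#' @examples
#' hypothesis_spec(0.03, 0.03, 0.10, 0.15)
#' @export
hypothesis_spec <- function(p0_neg, p0_pos, p1_neg, p1_pos) {
  rates <- c(p0_neg = p0_neg, p0_pos = p0_pos,
             p1_neg = p1_neg, p1_pos = p1_pos)
  if (any(!is.finite(rates) | rates < 0 | rates > 1))
    stop("all response rates must lie in [0, 1]", call. = FALSE)
  if (p0_neg >= p1_neg)
    stop("p1_neg must exceed p0_neg", call. = FALSE)
  if (p0_pos >= p1_pos)
    stop("p1_pos must exceed p0_pos", call. = FALSE)
  if (p1_neg > p1_pos)
    stop("order restriction violated: p1_neg must not exceed p1_pos",
         call. = FALSE)
  structure(as.list(rates), class = "hypothesis_spec")
}

#' @export
print.hypothesis_spec <- function(x, ...) {
  cat(sprintf("Hypotheses: H0-: p- = %g, H0+: p+ = %g; targets p1- = %g, p1+ = %g\n",
              x$p0_neg, x$p0_pos, x$p1_neg, x$p1_pos))
  invisible(x)
}

.check_rate <- function(p, name) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop(name, " must lie in [0, 1]", call. = FALSE)
  p
}

.check_design <- function(d) {
  if (!inherits(d, "stratified_design")) {
    if (is.character(d) && length(d) == 1L) return(parse_design(d))
    stop("expected a 'stratified_design' or a design string", call. = FALSE)
  }
  d
}
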