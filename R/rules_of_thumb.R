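# Order-of-magnitude heuristics for the expected p-value attainable by
# enlarging a study: the squaring rule (very many controls per case) and
# the doubling rule (equivalence with doubling the cases at 1:1).
# Advisory helpers only -- never used inside the exact calculations.

#' Squaring rule: expected p-value at very many controls per case
#'
#' Heuristic: the order of magnitude of the median expected p-value at a
#' very large controls/case ratio is roughly the square of the median
#' expected p-value at 1 control per case.  Computed in log10 space, so
#' inputs near the underflow limit square without loss.
#'
#' @param p_j1 Median expected p-value at 1 control per case, in (0, 1].
#' @return The rule's prediction, \eqn{p_{J=1}^2} (0 if it underflows;
#'   use [squaring_rule_log10()] for the always-finite log10 version).
#' @examples
#' squaring_rule(1e-8)   # 1e-16
#' @export
squaring_rule <- function(p_j1) {
  10^squaring_rule_log10(p_j1)
}

#' @rdname squaring_rule
#' @export
squaring_rule_log10 <- function(p_j1) {
  if (!is.numeric(p_j1) || any(!is.finite(p_j1)) ||
      any(p_j1 <= 0) || any(p_j1 > 1)) {
    stop("'p_j1' must be a p-value in (0, 1]", call. = FALSE)
  }
  2 * log10(p_j1)
}

#' Doubling rule: many controls versus doubling the cases
#'
#' Heuristic: recruiting a very large number of controls per case yields
#' about the same median expected p-value as doubling the number of cases
#' while keeping 1 control per case.  This checks the rule on a concrete
#' design: it computes the exact expected p-value with `2 n` cases at
#' \eqn{J = 1} and with `n` cases at \eqn{J =} `j_large`, and reports
#' both with their log10 gap.
#'
#' @param d An [allele_design()] with `controls_per_case = 1`.
#' @param j_large The ratio standing in for "very many controls"
#'   (default 1000, where the OR-reduction asymptote of 29.3\% is nearly
#'   attained).
#' @return A data frame with one row: `p_j1` (the design as given),
#'   `p_doubled_cases`, `p_large_j`, their log10 columns, and
#'   `log10_gap = |log10 p_doubled - log10 p_largeJ|`.
#' @examples
#' d <- allele_design(5000, 1, maf_controls = 0.5, odds_ratio = 1.1)
#' doubling_rule(d)   # gap well under one order of magnitude
#' @export
doubling_rule <- function(d, j_large = 1000) {
  stopifnot(inherits(d, "allele_design"))
  if (d$controls_per_case != 1) {
    stop("the doubling rule compares designs anchored at 1 control/case",
         call. = FALSE)
  }
  base <- expected_pvalue_gwas(d)
  doubled <- expected_pvalue_gwas(allele_design(
    2 * d$n_cases, 1, d$maf_controls, d$odds_ratio, d$alpha))
  large <- expected_pvalue_gwas(allele_design(
    d$n_cases, j_large, d$maf_controls, d$odds_ratio, d$alpha))
  data.frame(
    n_cases = d$n_cases, maf_controls = d$maf_controls,
    odds_ratio = d$odds_ratio, alpha = d$alpha, j_large = j_large,
    p_j1 = base$median_p, log10_p_j1 = base$log10_median_p,
    p_doubled_cases = doubled$median_p,
    log10_p_doubled_cases = doubled$log10_median_p,
    p_large_j = large$median_p, log10_p_large_j = large$log10_median_p,
    log10_gap = abs(doubled$log10_median_p - large$log10_median_p)
  )
}

#' Check both rules of thumb against the exact model
#'
#' For a 1-control-per-case design, compares the squaring-rule and
#' doubling-rule predictions against the exact expected p-value at
#' `j_large` controls per case, reporting log10 gaps.  The rules are
#' order-of-magnitude guides: over common GWAS design ranges they land
#' within about one order of magnitude of the exact value once
#' \eqn{p_{J=1} \lesssim 10^{-3}}.
#'
#' @inheritParams doubling_rule
#' @return A data frame with one row combining both rules: the exact
#'   `p_j1` and `p_large_j`, the squaring prediction and its
#'   `squaring_log10_gap`, and the doubling comparison with its
#'   `doubling_log10_gap`.
#' @export
rules_check <- function(d, j_large = 1000) {
  dbl <- doubling_rule(d, j_large)
  sq_l10 <- squaring_rule_log10(dbl$p_j1)
  cbind(
    dbl[c("n_cases", "maf_controls", "odds_ratio", "alpha", "j_large",
          "p_j1", "log10_p_j1", "p_large_j", "log10_p_large_j")],
    data.frame(
      p_squared = 10^sq_l10,
      squaring_log10_gap = abs(sq_l10 - dbl$log10_p_large_j),
      p_doubled_cases = dbl$p_doubled_cases,
      doubling_log10_gap = dbl$log10_gap
    )
  )
}
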