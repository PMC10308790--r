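# Explicit allele-based power model for GWAS case-control designs:
# two-proportion score test on allele counts, with Wald variant,
# median expected p-values, and minimum-detectable-OR inversion.

#' Allele frequency in cases implied by a control frequency and an OR
#'
#' Standard logit algebra: if the control (minor) allele frequency is
#' \eqn{p_2} and the allelic odds ratio is \eqn{OR}, the case allele
#' frequency is \eqn{p_1 = OR\,p_2 / \{1 + p_2(OR - 1)\}}, i.e. the unique
#' frequency whose odds are \eqn{OR} times the control odds.
#'
#' @param p2 Control allele frequency, strictly in (0, 1).  Vectorized.
#' @param odds_ratio Allelic odds ratio, > 0.  Vectorized with `p2`.
#' @return Case allele frequency in (0, 1).
#' @examples
#' case_allele_frequency(0.5, 1.1)          # 0.5238
#' # round-trips: implied odds ratio is recovered exactly
#' p1 <- case_allele_frequency(0.185, 1.48)
#' (p1 / (1 - p1)) / (0.185 / (1 - 0.185))  # 1.48
#' @export
case_allele_frequency <- function(p2, odds_ratio) {
  check_prob(p2, "p2")
  if (!is.numeric(odds_ratio) || any(!is.finite(odds_ratio)) ||
      any(odds_ratio <= 0)) {
    stop("'odds_ratio' must be positive and finite", call. = FALSE)
  }
  odds_ratio * p2 / (1 + p2 * (odds_ratio - 1))
}

#' GWAS case-control design on the allele scale
#'
#' Describes a single-marker association design: `n_cases` cases with
#' `controls_per_case` controls each, a control minor allele frequency, an
#' allelic odds ratio, and a two-sided significance level.  Under
#' Hardy-Weinberg equilibrium each subject contributes two independent
#' alleles, so the test operates on \eqn{n_1 = 2\,\mathrm{cases}} case
#' alleles versus \eqn{n_2 = 2\,\mathrm{cases}\,J} control alleles.
#'
#' Frequencies above 0.5 are folded to the minor allele (`1 - maf`) with a
#' warning; the two-proportion test is symmetric in the allele labelling.
#'
#' @param n_cases Number of case subjects (> 0).
#' @param controls_per_case Controls per case \eqn{J}, real \eqn{\ge} 1.
#' @param maf_controls Control minor allele frequency, in (0, 0.5].
#' @param odds_ratio Allelic odds ratio, > 0.
#' @param alpha Two-sided type-1 error (default `5e-8`, the conventional
#'   genome-wide significance level).
#' @return An object of class `"allele_design"`: a list with the supplied
#'   parameters plus the derived allele counts `n1`, `n2` and frequencies
#'   `p1` (cases), `p2` (controls).
#' @examples
#' d <- allele_design(10000, controls_per_case = 4, maf_controls = 0.5,
#'                    odds_ratio = 1.1)
#' score_test_power(d)
#' @export
allele_design <- function(n_cases, controls_per_case = 1, maf_controls,
                          odds_ratio, alpha = 5e-8) {
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases <= 0) {
    stop("'n_cases' must be a single positive count", call. = FALSE)
  }
  check_ratio(controls_per_case)
  check_prob(maf_controls, "maf_controls")
  if (maf_controls > 0.5) {
    warning("'maf_controls' > 0.5; folding to the minor allele (1 - maf)",
            call. = FALSE)
    maf_controls <- 1 - maf_controls
  }
  if (!is.numeric(odds_ratio) || length(odds_ratio) != 1L ||
      !is.finite(odds_ratio) || odds_ratio <= 0) {
    stop("'odds_ratio' must be a single positive value", call. = FALSE)
  }
  check_prob(alpha, "alpha")
  p2 <- maf_controls
  structure(list(
    n_cases = n_cases,
    controls_per_case = controls_per_case,
    maf_controls = p2,
    odds_ratio = odds_ratio,
    alpha = alpha,
    n1 = 2 * n_cases,
    n2 = 2 * n_cases * controls_per_case,
    p1 = case_allele_frequency(p2, odds_ratio),
    p2 = p2
  ), class = "allele_design")
}

#' @export
print.allele_design <- function(x, ...) {
  cat("Allele-based GWAS case-control design\n")
  cat(sprintf("  cases: %g  controls/case: %g  (alleles: %g vs %g)\n",
              x$n_cases, x$controls_per_case, x$n1, x$n2))
  cat(sprintf("  control MAF: %g  OR: %g  ->  case freq: %.6g\n",
              x$p2, x$odds_ratio, x$p1))
  cat(sprintf("  two-sided alpha: %g\n", x$alpha))
  invisible(x)
}

#' Null and alternative standard deviations of the frequency difference
#'
#' The two-proportion test statistic divides the observed case-control
#' allele-frequency difference by its null standard deviation.  For power
#' both standard deviations are needed:
#' \deqn{\phi_1 = \sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}, \qquad
#'       \phi_0 = \sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)},}
#' with \eqn{\bar p} the allele-count-weighted pooled frequency.  These are
#' the general unequal-group forms; for equal groups (\eqn{J = 1}) they
#' collapse to the familiar \eqn{\sqrt{2N}}-scaled expressions.  At
#' \eqn{OR = 1} the two coincide.
#'
#' @param d An [allele_design()].
#' @return A list with elements `phi0` (null SD) and `phi1`
#'   (alternative SD).
#' @export
variance_decomposition <- function(d) {
  stopifnot(inherits(d, "allele_design"))
  p1 <- d$p1; p2 <- d$p2; n1 <- d$n1; n2 <- d$n2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  list(phi0 = sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2)),
       phi1 = sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2))
}

# Signed power deviate Z_{1-beta}; shared by the power and p-value ops.
# "score": null SD in the critical-value term, alternative SD as the SD of
# the frequency difference -- the power of the pooled-variance score test,
# verified against simulation.  "wald": alternative SD in both places.
# "swapped": the two SDs interchanged relative to "score"; not the power
# of either test, but the convention behind widely circulated reference
# tables of minimum detectable ORs (see min_detectable_or).
power_deviate <- function(d, method = c("score", "wald", "swapped")) {
  method <- match.arg(method)
  v <- variance_decomposition(d)
  za <- two_sided_crit_value(d$alpha)
  delta <- abs(d$p1 - d$p2)
  switch(method,
         score = (delta - za * v$phi0) / v$phi1,
         wald = (delta - za * v$phi1) / v$phi1,
         swapped = (delta - za * v$phi1) / v$phi0)
}

#' Power of the allele-based two-proportion test
#'
#' Power of the two-sided level-\eqn{\alpha} test of equal allele
#' frequencies in cases and controls, from the normal approximation
#' \deqn{Z_{1-\beta} = \frac{|p_1 - p_2| - \phi_0 Z_{1-\alpha/2}}{\phi_1},
#'   \qquad \mathrm{power} = \Phi(Z_{1-\beta}).}
#' `score_test_power()` uses the pooled null standard deviation
#' \eqn{\phi_0} in the critical-value term, which matches the score test
#' actually computed from a 2x2 table.  `wald_test_power()` substitutes the
#' alternative standard deviation \eqn{\phi_1} (the convention of some
#' popular genetic power calculators), appropriate for a Wald test.  The
#' two agree at \eqn{OR = 1}, where both return \eqn{\alpha/2}, the
#' one-tail rejection probability; only the favourable tail is counted.
#'
#' @param d An [allele_design()].
#' @return Power in (0, 1).
#' @examples
#' d <- allele_design(10000, 1, maf_controls = 0.5, odds_ratio = 1.13)
#' score_test_power(d)   # about 0.80 at genome-wide significance
#' wald_test_power(d)    # slightly different critical-value convention
#' @export
score_test_power <- function(d) {
  stats::pnorm(power_deviate(d, "score"))
}

#' @rdname score_test_power
#' @export
wald_test_power <- function(d) {
  stats::pnorm(power_deviate(d, "wald"))
}

#' @rdname score_test_power
#' @details
#' `swapped_sd_power()` evaluates the variant in which the two standard
#' deviations trade places: the alternative SD \eqn{\phi_1} in the
#' critical-value term and the null SD \eqn{\phi_0} as the SD of the
#' frequency difference.  It is not the power of either the score or the
#' Wald test -- simulation of the actual pooled-variance score test agrees
#' with `score_test_power()` -- but it is the convention that generated
#' widely used reference tables of minimum detectable ORs, and it is
#' conservative (understates power) for unbalanced designs with rare
#' alleles.  It is provided so those tables can be reproduced and the
#' three conventions compared.
#' @export
swapped_sd_power <- function(d) {
  stats::pnorm(power_deviate(d, "swapped"))
}

#' Median expected p-value for a GWAS design
#'
#' The median expected two-sided p-value of the allele-based score test,
#' obtained by feeding the signed power deviate of [score_test_power()]
#' into the median-p formula \eqn{2\Phi(-|Z_{1-\beta} + Z_{1-\alpha/2}|)}.
#' The signed deviate is retained, so under-powered designs correctly
#' yield a median expected p-value above \eqn{\alpha}.
#'
#' @param d An [allele_design()].
#' @return A data frame with one row: `power`, `median_p`,
#'   `log10_median_p`.  `median_p` is 0 when the value underflows double
#'   precision; `log10_median_p` always remains finite.
#' @examples
#' d <- allele_design(5000, 1, maf_controls = 0.5, odds_ratio = 1.1)
#' expected_pvalue_gwas(d)   # median p about 8e-4
#' @export
expected_pvalue_gwas <- function(d) {
  zb <- power_deviate(d, "score")
  za <- two_sided_crit_value(d$alpha)
  l10 <- (log(2) + stats::pnorm(-abs(zb + za), log.p = TRUE)) / log(10)
  data.frame(power = stats::pnorm(zb), median_p = 10^l10,
             log10_median_p = l10)
}

#' Minimum detectable odds ratio for a GWAS design
#'
#' Inverts the allele-based power model in the odds ratio: the unique
#' \eqn{OR > 1} at which the design attains `target_power` at two-sided
#' level `alpha`.  Power is strictly increasing in \eqn{OR > 1}, so the
#' root is unique; it is found by bracketed root search on \eqn{\log OR}
#' with absolute tolerance 1e-10.
#'
#' `method` selects the power convention inverted: `"score"` (default)
#' inverts [score_test_power()], the simulation-validated power of the
#' pooled-variance score test; `"wald"` inverts [wald_test_power()];
#' `"swapped"` inverts [swapped_sd_power()], the interchanged-SD
#' convention behind established reference tables (conservative for rare
#' alleles in unbalanced designs -- at 2,500 cases, 4 controls/case and
#' MAF 0.01 it gives 2.42 where the score test truly detects 2.15).
#'
#' @param n_cases Number of case subjects.
#' @param j Controls per case, real \eqn{\ge} 1.
#' @param maf_controls Control minor allele frequency in (0, 0.5].
#' @param alpha Two-sided type-1 error (default genome-wide `5e-8`).
#' @param target_power Power to attain (default 0.8).
#' @param or_max Upper bracket for the search (default 100).
#' @param method Power convention; one of `"score"`, `"wald"`,
#'   `"swapped"`.
#' @return The minimum detectable odds ratio (> 1).
#' @examples
#' min_detectable_or(10000, 1, 0.5)    # 1.13
#' min_detectable_or(10000, 50, 0.5)   # 1.094
#' @export
min_detectable_or <- function(n_cases, j, maf_controls, alpha = 5e-8,
                              target_power = 0.8, or_max = 100,
                              method = c("score", "wald", "swapped")) {
  method <- match.arg(method)
  check_prob(target_power, "target_power")
  if (target_power <= alpha) {
    stop("'target_power' must exceed 'alpha'", call. = FALSE)
  }
  f <- function(log_or) {
    stats::pnorm(power_deviate(
      allele_design(n_cases, j, maf_controls, exp(log_or), alpha),
      method)) - target_power
  }
  hi <- log(or_max)
  if (f(hi) < 0) {
    stop(sprintf(
      "design unattainable: power %.3g at OR = %g is below target %g",
      f(hi) + target_power, or_max, target_power), call. = FALSE)
  }
  # at log OR -> 0+ power -> alpha/2 < target, so the root is bracketed
  root <- stats::uniroot(f, lower = 1e-12, upper = hi, tol = 1e-10)$root
  exp(root)
}
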