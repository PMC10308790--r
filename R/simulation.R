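# Monte-Carlo checks of the asymptotic machinery: simulate allele-count
# 2x2 tables, compute the pooled-variance score statistic, and estimate
# type-1 error, power, median p-value and statistic skewness.

#' Simulate allele-count tables for a GWAS design
#'
#' Draws independent replicate 2x2 allele-count tables: case minor-allele
#' counts from Binomial(\eqn{n_1}, \eqn{p_1}) and control counts from
#' Binomial(\eqn{n_2}, \eqn{p_2}), with \eqn{n_1, n_2, p_1, p_2} taken
#' from the design.  The stream is fully reproducible given `seed`.
#'
#' @param d An [allele_design()].
#' @param n_reps Number of replicate tables, \eqn{\ge} 1.
#' @param seed Integer RNG seed; if `NULL` the current RNG state is used.
#' @return A data frame with `n_reps` rows: `case_count`, `control_count`.
#' @export
simulate_tables <- function(d, n_reps, seed = NULL) {
  stopifnot(inherits(d, "allele_design"))
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    stop("'n_reps' must be a single count >= 1", call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  if (!is.null(seed)) set.seed(as.integer(seed))
  data.frame(
    case_count = stats::rbinom(n_reps, d$n1, d$p1),
    control_count = stats::rbinom(n_reps, d$n2, d$p2)
  )
}

#' Two-proportion score statistic for an allele-count table
#'
#' The pooled-variance score statistic for a 2x2 allele-count table:
#' \deqn{Z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat{\bar p}(1-\hat{\bar p})(1/n_1 + 1/n_2)}},}
#' with the two-sided p-value \eqn{2\Phi(-|Z|)}.  Degenerate tables
#' (pooled frequency 0 or 1, so the null variance estimate vanishes)
#' carry no evidence against the null and return \eqn{Z = 0, p = 1}.
#'
#' @param case_count Minor-allele count(s) among case alleles.
#' @param control_count Minor-allele count(s) among control alleles.
#' @param n1 Number of case alleles.
#' @param n2 Number of control alleles.
#' @return A data frame with columns `z` (signed statistic) and `p`
#'   (two-sided p-value).
#' @examples
#' score_statistic(120, 80, 2000, 2000)
#' @export
score_statistic <- function(case_count, control_count, n1, n2) {
  if (any(case_count < 0) || any(case_count > n1) ||
      any(control_count < 0) || any(control_count > n2)) {
    stop("counts must lie in [0, n] for their arm", call. = FALSE)
  }
  p1 <- case_count / n1
  p2 <- control_count / n2
  pbar <- (case_count + control_count) / (n1 + n2)
  v <- pbar * (1 - pbar) * (1 / n1 + 1 / n2)
  z <- ifelse(v > 0, (p1 - p2) / sqrt(v), 0)
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# third standardized moment
statistic_skewness <- function(z) {
  m <- mean(z)
  s <- stats::sd(z)
  mean((z - m)^3) / s^3
}

#' Monte-Carlo calibration report for a GWAS design
#'
#' Checks the asymptotic machinery by simulation.  For each requested
#' \eqn{\alpha}: the empirical type-1 error (rejection fraction of the
#' score test under \eqn{OR = 1}), the empirical power under the design's
#' odds ratio, the empirical median p-value under the alternative, and the
#' skewness of the null score statistics, each with its Monte-Carlo
#' standard error.  A design is flagged `valid` at a level when the
#' empirical type-1 error falls within `band_se` Monte-Carlo standard
#' errors of the nominal level and the null-statistic skewness is below
#' `skew_threshold` in magnitude; rare alleles with few cases fail this,
#' and adding controls does not rescue them.
#'
#' When the expected number of null rejections `n_reps * alpha` is below
#' 5, the type-1 error estimate is too noisy to be meaningful and a
#' warning is issued (the row is still reported).
#'
#' @param d An [allele_design()]; its `alpha` is ignored in favour of
#'   `alpha_grid`.
#' @param n_reps Replicates per condition (default `1e5`).
#' @param seed Integer RNG seed for the whole report.
#' @param alpha_grid Levels at which to estimate rejection rates.
#' @param skew_threshold Maximum tolerated |skewness| of the null
#'   statistic (default 0.1).
#' @param band_se Half-width of the validity band in Monte-Carlo standard
#'   errors (default 3).
#' @return A data frame, one row per level: design parameters, `alpha`,
#'   `empirical_type1`, `type1_se`, `empirical_power`, `power_se`,
#'   `analytic_power`, `median_p`, `analytic_median_p`, `skewness`,
#'   `valid`.
#' @examples
#' \donttest{
#' d <- allele_design(10000, 1, maf_controls = 0.5, odds_ratio = 1.1)
#' validity_report(d, n_reps = 1e4, seed = 1, alpha_grid = c(0.05, 1e-3))
#' }
#' @export
validity_report <- function(d, n_reps = 1e5, seed = NULL,
                            alpha_grid = c(0.05, 1e-3, 1e-4),
                            skew_threshold = 0.1, band_se = 3) {
  stopifnot(inherits(d, "allele_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  d_null <- allele_design(d$n_cases, d$controls_per_case, d$maf_controls,
                          odds_ratio = 1, alpha = d$alpha)
  tab0 <- simulate_tables(d_null, n_reps)
  tab1 <- simulate_tables(d, n_reps)
  s0 <- score_statistic(tab0$case_count, tab0$control_count, d$n1, d$n2)
  s1 <- score_statistic(tab1$case_count, tab1$control_count, d$n1, d$n2)
  skew <- statistic_skewness(s0$z)

  rows <- lapply(alpha_grid, function(a) {
    if (n_reps * a < 5) {
      warning(sprintf(
        "n_reps = %g gives < 5 expected null rejections at alpha = %g; %s",
        n_reps, a, "the type-1 error estimate is unreliable"),
        call. = FALSE)
    }
    t1 <- mean(s0$p < a)
    pw <- mean(s1$p < a)
    t1_se <- sqrt(t1 * (1 - t1) / n_reps)
    pw_se <- sqrt(pw * (1 - pw) / n_reps)
    an_pw <- score_test_power(allele_design(
      d$n_cases, d$controls_per_case, d$maf_controls, d$odds_ratio, a))
    an_mp <- median_p(an_pw, a)
    data.frame(
      n_cases = d$n_cases, controls_per_case = d$controls_per_case,
      maf_controls = d$maf_controls, odds_ratio = d$odds_ratio,
      n_reps = n_reps, alpha = a,
      empirical_type1 = t1, type1_se = t1_se,
      empirical_power = pw, power_se = pw_se, analytic_power = an_pw,
      median_p = stats::median(s1$p), analytic_median_p = an_mp,
      skewness = skew,
      valid = abs(t1 - a) <= band_se * sqrt(a * (1 - a) / n_reps) &&
        abs(skew) < skew_threshold
    )
  })
  do.call(rbind, rows)
}
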