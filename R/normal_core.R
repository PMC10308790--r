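# Closed-form normal-approximation engine: power transfer across
# controls/case ratios, median expected p-values under the alternative,
# and the ratio-only shrinkage of the minimum detectable odds ratio.

#' Standard normal quantile, stable near 1
#'
#' Returns \eqn{Z_x = \Phi^{-1}(x)}, the standard normal quantile at
#' probability `x`.  For `x` close to 1 (e.g. `1 - 2.5e-9`, the two-sided
#' critical level at genome-wide significance) the quantile is evaluated
#' through the complement's upper tail, avoiding the catastrophic
#' cancellation that `qnorm(x)` suffers when `1 - x` underflows the mantissa.
#'
#' When the level arises as \eqn{1 - \alpha/2}, prefer
#' [two_sided_crit_value()], which takes \eqn{\alpha} directly and never
#' forms the complement at all.
#'
#' @param x Probability (or vector of probabilities), strictly in (0, 1).
#' @return Numeric vector of standard normal quantiles.
#' @examples
#' z_quantile(0.8)                 # 0.8416
#' z_quantile(1 - 5e-8 / 2)        # 5.4513, genome-wide critical deviate
#' @export
z_quantile <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop("'x' must be a probability strictly inside (0, 1)", call. = FALSE)
  }
  ifelse(x > 0.5, stats::qnorm(1 - x, lower.tail = FALSE), stats::qnorm(x))
}

#' Two-sided critical deviate
#'
#' The upper critical value \eqn{Z_{1-\alpha/2}} of a two-sided level-\eqn{\alpha}
#' normal test, computed from \eqn{\alpha} via the upper tail so that
#' arbitrarily small \eqn{\alpha} (down to the smallest positive double)
#' keep full precision.
#'
#' @param alpha Two-sided type-1 error, strictly in (0, 1).  Vectorized.
#' @return Numeric vector of critical deviates.
#' @examples
#' two_sided_crit_value(0.05)   # 1.96
#' two_sided_crit_value(5e-8)   # 5.45
#' @export
two_sided_crit_value <- function(alpha) {
  check_prob(alpha, "alpha")
  stats::qnorm(alpha / 2, lower.tail = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(sprintf("'%s' must be strictly inside (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}

check_ratio <- function(j) {
  if (!is.numeric(j) || any(!is.finite(j)) || any(j < 1)) {
    stop("controls/case ratio 'j' must be a finite number >= 1", call. = FALSE)
  }
  invisible(j)
}

#' Design point for ratio-only power transfer
#'
#' Bundles the three quantities that determine power under local
#' alternatives: the two-sided type-1 error \eqn{\alpha}, the power the
#' design attains with 1 control per case, and the controls/case ratio
#' \eqn{J}.  Under local alternatives (detectable effects shrinking toward
#' the null as samples grow) the sample sizes, exposure frequencies and
#' odds ratio enter only through the power at \eqn{J = 1}, so this triple
#' is the complete design description.
#'
#' @param alpha Two-sided type-1 error in (0, 1).
#' @param power_j1 Power with 1 control per case, in (0, 1).
#' @param j Controls per case; any real \eqn{\ge} 1 (the formulas are
#'   continuous in `j`).  May be a vector.
#' @return An object of class `"design_point"`: a list with elements
#'   `alpha`, `power_j1`, `j`.
#' @seealso [power_at_ratio()], [power_curve()]
#' @export
design_point <- function(alpha, power_j1, j = 1) {
  check_prob(alpha, "alpha")
  check_prob(power_j1, "power_j1")
  check_ratio(j)
  structure(list(alpha = alpha, power_j1 = power_j1, j = j),
            class = "design_point")
}

#' @export
print.design_point <- function(x, ...) {
  cat("Case-control design point (local alternatives)\n")
  cat(sprintf("  two-sided alpha : %g\n", x$alpha))
  cat(sprintf("  power at J = 1  : %g\n", x$power_j1))
  cat(sprintf("  controls/case J : %s\n", paste(format(x$j), collapse = ", ")))
  invisible(x)
}

#' Power at J controls per case from power at 1 control per case
#'
#' Transfers the power of a two-sided level-\eqn{\alpha} test from a
#' 1-control-per-case design to \eqn{J} controls per case:
#' \deqn{1-\beta_J = \Phi\!\left(Z_{1-\beta_1} +
#'   \{Z_{1-\beta_1} + Z_{1-\alpha/2}\}\{\sqrt{2J/(J+1)} - 1\}\right).}
#' The transfer holds under local alternatives, where the combination of
#' sample sizes, exposure frequencies and odds ratio is subsumed by the
#' power at \eqn{J = 1}.  Power is reported for the favourable tail only;
#' the neglected opposite-tail rejection probability is below
#' \eqn{\Phi(-Z_{1-\beta}-Z_{1-\alpha/2})} and is negligible for every
#' \eqn{\alpha} in common use.
#'
#' @param power_j1 Power with 1 control per case, in (0, 1).  Alternatively
#'   a [design_point()] object, in which case the other arguments are
#'   ignored.
#' @param alpha Two-sided type-1 error in (0, 1).
#' @param j Controls per case, real \eqn{\ge} 1.  Vectorized.
#' @return Power at `j` controls per case, in (0, 1).
#' @examples
#' # an underpowered genome-wide design gains a lot from extra controls:
#' power_at_ratio(0.2, 5e-8, c(1, 4, 10, 50))
#' # at alpha = 0.05 the gain saturates quickly (the classical 4:1 rule):
#' power_at_ratio(0.2, 0.05, c(4, 100))
#' @export
power_at_ratio <- function(power_j1, alpha, j) {
  if (inherits(power_j1, "design_point")) {
    d <- power_j1
    return(power_at_ratio(d$power_j1, d$alpha, d$j))
  }
  check_prob(power_j1, "power_j1")
  check_prob(alpha, "alpha")
  check_ratio(j)
  zb1 <- stats::qnorm(power_j1)
  za <- two_sided_crit_value(alpha)
  stats::pnorm(zb1 + (zb1 + za) * (sqrt(2 * j / (j + 1)) - 1))
}

# Signed log10 median expected p-value; the numerical core shared by the
# public accessors.  Works entirely in log space so that p-values far below
# the double underflow limit remain meaningful on the log10 scale.
median_p_log10_core <- function(power, alpha) {
  zb <- stats::qnorm(power)
  za <- two_sided_crit_value(alpha)
  (log(2) + stats::pnorm(-abs(zb + za), log.p = TRUE)) / log(10)
}

#' Median expected p-value under the alternative
#'
#' The p-value of a replicated study is itself random; under the
#' alternative its distribution is skewed toward 0 and its median is
#' \deqn{p = 2\,\Phi(-|Z_{1-\beta} + Z_{1-\alpha/2}|),}
#' the p-value one should typically expect for an association with power
#' \eqn{1-\beta} tested at two-sided level \eqn{\alpha}.  At 50\% power the
#' median expected p-value equals \eqn{\alpha} exactly; it is below
#' \eqn{\alpha} precisely when power exceeds 50\%.
#'
#' `median_p()` returns the p-value itself (0 once the value underflows
#' double precision, below roughly 1e-320); `median_p_log10()` returns
#' \eqn{\log_{10} p}, which stays finite for arbitrarily extreme designs
#' and is the scale to use for fold-change comparisons.
#'
#' @param power Power of the test under the alternative, in (0, 1).
#' @param alpha Two-sided type-1 error in (0, 1).  Vectorized with `power`.
#' @return `median_p()`: the median expected two-sided p-value.
#'   `median_p_log10()`: its base-10 logarithm.
#' @examples
#' median_p(0.8, 0.05)     # 0.0051
#' median_p(0.8, 5e-8)     # 3.1e-10
#' median_p(0.5, 1e-4)     # exactly alpha at 50% power
#' @export
median_p <- function(power, alpha) {
  check_prob(power, "power")
  10^median_p_log10_core(power, alpha)
}

#' @rdname median_p
#' @export
median_p_log10 <- function(power, alpha) {
  check_prob(power, "power")
  median_p_log10_core(power, alpha)
}

#' Power curve and expected p-values across controls/case ratios
#'
#' Composes [power_at_ratio()] and [median_p()] over a grid of
#' controls/case ratios, giving the full picture of what extra controls buy
#' a fixed set of cases: the power and the median expected p-value at each
#' ratio.
#'
#' @inheritParams power_at_ratio
#' @param j Vector of controls/case ratios; defaults to the standard
#'   reporting grid.
#' @return A data frame with one row per ratio and columns `j`, `power`,
#'   `median_p`, `log10_median_p`.
#' @examples
#' power_curve(0.2, 5e-8, j = c(1, 4, 10, 50))
#' @export
power_curve <- function(power_j1, alpha,
                        j = c(1, 2, 3, 4, 5, 10, 20, 50, 100, 1000)) {
  if (inherits(power_j1, "design_point")) {
    d <- power_j1
    return(power_curve(d$power_j1, d$alpha, d$j))
  }
  pw <- power_at_ratio(power_j1, alpha, j)
  l10 <- median_p_log10_core(pw, alpha)
  data.frame(j = j, power = pw, median_p = 10^l10, log10_median_p = l10)
}

#' Fractional reduction of the minimum detectable OR toward the null
#'
#' Moving from 1 to \eqn{J} controls per case shrinks the minimum
#' detectable odds ratio toward the null by the fraction
#' \deqn{\frac{OR_1 - OR_J}{OR_1 - 1} \approx 1 - \sqrt{\frac{J+1}{2J}},}
#' a result valid for small associations that depends only on the ratio
#' \eqn{J}: power, \eqn{\alpha}, marker frequencies and sample sizes are
#' all subsumed into \eqn{OR_1}.  It therefore applies equally to
#' classical \eqn{\alpha = 0.05} epidemiology and to genome-wide testing.
#' The reduction asymptotes at \eqn{1 - \sqrt{1/2} \approx 29.3\%}.
#'
#' @param j Controls per case, real \eqn{\ge} 1.  Vectorized.
#' @return The fractional reduction, in \eqn{[0, 1 - \sqrt{1/2})}.
#' @examples
#' or_reduction_fraction(4)      # 0.209: 20.9% of the way to the null
#' or_reduction_fraction(1000)   # 0.293: essentially the asymptote
#' @export
or_reduction_fraction <- function(j) {
  check_ratio(j)
  1 - sqrt((j + 1) / (2 * j))
}

#' Minimum detectable OR at J controls per case from the OR at 1:1
#'
#' Applies the ratio-only shrinkage of [or_reduction_fraction()] to a
#' concrete minimum detectable odds ratio: \eqn{OR_J = OR_1 - (OR_1 - 1)
#' \{1 - \sqrt{(J+1)/(2J)}\}}.  Also reports the additional fractional
#' reduction relative to a baseline ratio (default 4 controls/case, the
#' classical design), \eqn{(OR_{J_0} - OR_J)/(OR_{J_0} - 1)}.
#'
#' Protective odds ratios (\eqn{OR_1 < 1}) are handled by mapping to the
#' reciprocal, shrinking, and inverting back; the shrinkage formula is
#' derived for toward-the-null movement of an OR above 1.
#'
#' @param or_j1 Minimum detectable odds ratio with 1 control per case;
#'   any positive value other than 1.
#' @param j Controls per case, real \eqn{\ge} 1.  Vectorized.
#' @param j_baseline Baseline ratio for the incremental comparison
#'   (default 4).
#' @return An object of class `"or_reduction"`: a data frame with columns
#'   `or_j1`, `j`, `or_j`, `fraction_vs_j1`, `fraction_vs_baseline` and
#'   attribute `j_baseline`.
#' @examples
#' # an OR of 2 detectable at 1:1 becomes 1.71 with very many controls:
#' min_detectable_or_at_ratio(2, j = 1000)
#' # moving 4 -> 50 controls/case gains a further 9.7% toward the null:
#' min_detectable_or_at_ratio(1.5, j = 50, j_baseline = 4)
#' @export
min_detectable_or_at_ratio <- function(or_j1, j, j_baseline = 4) {
  if (!is.numeric(or_j1) || length(or_j1) != 1L || !is.finite(or_j1) ||
      or_j1 <= 0 || or_j1 == 1) {
    stop("'or_j1' must be a single positive OR different from 1",
         call. = FALSE)
  }
  check_ratio(j)
  check_ratio(j_baseline)
  protective <- or_j1 < 1
  or1 <- if (protective) 1 / or_j1 else or_j1
  shrink <- function(jj) or1 - (or1 - 1) * or_reduction_fraction(jj)
  or_j <- shrink(j)
  or_base <- shrink(j_baseline)
  frac1 <- (or1 - or_j) / (or1 - 1)
  fracb <- (or_base - or_j) / (or_base - 1)
  if (protective) or_j <- 1 / or_j
  structure(
    data.frame(or_j1 = or_j1, j = j, or_j = or_j,
               fraction_vs_j1 = frac1, fraction_vs_baseline = fracb),
    j_baseline = j_baseline,
    class = c("or_reduction", "data.frame")
  )
}
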