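---
title: "Designing case–control studies with many controls per case"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing case–control studies with many controls per case}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccpower)
```

## The problem

Classical epidemiology teaches that recruiting more than about 4
controls per case buys little power. That advice silently assumes a
type-1 error of 0.05. Modern association studies test enormous numbers
of hypotheses at far smaller levels — 2.5×10⁻⁶ for gene-based burden
tests, 5×10⁻⁸ or 5×10⁻⁹ for single-marker GWAS — and at such levels the
marginal value of additional controls is much larger. `ccpower`
quantifies that value on three scales a study designer cares about:
power, the p-value one should expect for a true association, and the
smallest odds ratio the design can detect.

## The ratio-only model and its assumptions

Let $1-\beta_1$ be the power of a two-sided level-$\alpha$ test with 1
control per case, and $J$ the controls/case ratio. Under **local
alternatives** — the asymptotic regime in which larger studies chase
proportionally smaller effects — the efficiency of a design enters only
through the variance of the case–control contrast, which scales as
$(1 + 1/J)$. Power therefore transfers across ratios as

$$1-\beta_J \;=\; \Phi\!\Big( Z_{1-\beta_1} +
  \big(Z_{1-\beta_1} + Z_{1-\alpha/2}\big)
  \big(\sqrt{2J/(J+1)} - 1\big) \Big),$$

implemented by `power_at_ratio()`. The appeal of this form is what it
*omits*: sample sizes, exposure frequencies and the odds ratio are all
subsumed by $1-\beta_1$, so one number summarises the design. The
$J$-factor $\sqrt{2J/(J+1)}-1$ is 0 at $J=1$ and rises to $\sqrt2-1$,
which caps how much any number of controls can achieve for a fixed set
of cases. Because the critical deviate $Z_{1-\alpha/2}$ multiplies the
$J$-factor, the gain from extra controls grows as $\alpha$ shrinks —
the quantitative content of the claim that the 4:1 rule is an
$\alpha=0.05$ artefact.

Two conventions worth stating. First, $Z_x \equiv \Phi^{-1}(x)$
throughout (so $Z_{0.8} \approx 0.84$ and
$Z_{1-\alpha/2} \approx 5.45$ at $\alpha = 5\times10^{-8}$). Second,
power is computed for the favourable tail only; the neglected
opposite-tail rejection probability is bounded by
$\Phi(-Z_{1-\beta}-Z_{1-\alpha/2})$, which is already below $10^{-3}$
at $\alpha = 0.05$ and utterly negligible at genome-wide levels.

A p-value is itself a random variable; under the alternative its
distribution is strongly right-skewed and its **median**,

$$p_{\text{med}} = 2\,\Phi\!\big(-|Z_{1-\beta} + Z_{1-\alpha/2}|\big),$$

is the natural "what should I expect to see" summary (`median_p()`).
At 50% power it equals $\alpha$ exactly, which makes the relation easy
to sanity-check and gives the useful reading that a design is
"expected-significant" precisely when its power exceeds one half.

For the minimum detectable odds ratio, a small-effect expansion of the
same variance scaling gives the ratio-only shrinkage

$$\frac{OR_1 - OR_J}{OR_1 - 1} \;\approx\; 1 - \sqrt{\frac{J+1}{2J}},$$

(`or_reduction_fraction()`), asymptoting at $1-\sqrt{1/2} = 29.3\%$:
with unlimited controls the detectable OR moves at most 29.3% of its
distance to the null, 20.9% of which is already claimed by $J=4$ and a
further 9.7% by $J=50$. Because $\alpha$, power and frequencies are
subsumed into $OR_1$, this statement holds for α = 0.05 epidemiology
just as for GWAS. Protective ORs are folded through the reciprocal
before shrinking, since the expansion is taken on the $OR>1$ side.

## The explicit GWAS model

The ratio-only model cannot answer "how many controls for *my* study".
For that, `allele_design()` describes a single-marker case–control
design explicitly: `n_cases` cases and `J` controls per case, a control
minor allele frequency $p_2$, and an allelic odds ratio, from which the
case frequency is $p_1 = OR\,p_2/\{1+p_2(OR-1)\}$. Under Hardy–Weinberg
equilibrium each subject contributes two independent alleles, so the
two-proportion test compares $n_1 = 2\,\text{cases}$ case alleles with
$n_2 = 2\,\text{cases}\,J$ control alleles. No genotypic
(dominance/recessive) models are offered; the model is agnostic of
genetic architecture beyond HWE.

With $\phi_1$ the standard deviation of $\hat p_1 - \hat p_2$ under the
alternative and $\phi_0$ its pooled-null counterpart (count-weighted
pooled frequency $\bar p$), the power deviate of the **score test** is

$$Z_{1-\beta} = \frac{|p_1 - p_2| - Z_{1-\alpha/2}\,\phi_0}{\phi_1}.$$

`ccpower` exposes three conventions, because all three circulate in
practice:

* `score_test_power()` — the form above. This is the power of the test
  people actually run on a 2×2 table (pooled-variance score/Pearson
  statistic). The package's Monte-Carlo machinery confirms it: over
  designs where the conventions disagree materially, empirical
  rejection rates of the simulated score test track this formula within
  Monte-Carlo error (see the test suite's simulation checks).
* `wald_test_power()` — $\phi_1$ substituted for $\phi_0$ in the
  critical-value term, appropriate for a Wald test and used by some
  popular genetic power calculators.
* `swapped_sd_power()` — the two SDs interchanged
  ($\phi_1$ in the critical term, $\phi_0$ in the denominator). This is
  **not** the power of either test, but it is demonstrably the
  convention behind widely circulated reference tables of minimum
  detectable ORs, which `table_min_or_gwas()` reproduces cell-for-cell
  by default. For rare alleles in unbalanced designs it is conservative:
  at 2,500 cases, $J=4$, MAF 0.01 it reports a minimum detectable OR of
  2.42 where the score test truly reaches 2.15. At MAF 0.5 the three
  conventions are practically indistinguishable.

The distinction matters only where $\phi_0$ and $\phi_1$ separate —
rare alleles, strong effects, unbalanced arms. `min_detectable_or()`
inverts any of the three conventions in the odds ratio
(`method = "score"` is its default; the table generator defaults to
`"swapped"` so that its output matches the published reference tables
it exists to regenerate).

For small effects the explicit model and the ratio-only shrinkage
agree: the fractional OR reductions from `min_detectable_or()` approach
$1-\sqrt{(J+1)/(2J)}$ as $OR_1 \to 1$, with the absolute gap on the
fraction scale below 0.01 once $OR_1 \le 1.1$. The approximation error
scales roughly with $OR_1 - 1$, so for large detectable effects
(rare alleles, few cases) the explicit model should be preferred.

## Monte-Carlo validation: what it emulates and what it does not

`simulate_tables()` draws replicate 2×2 allele-count tables —
case counts from $\mathrm{Bin}(n_1, p_1)$, control counts from
$\mathrm{Bin}(n_2, p_2)$ — and `score_statistic()` computes the
pooled-variance statistic with its two-sided p-value (degenerate
tables, where the pooled frequency is 0 or 1, carry no evidence and
return $p=1$). `validity_report()` wraps both into calibration
summaries: empirical type-1 error, power, median p-value, and the
skewness of the null statistic, each with its binomial Monte-Carlo
standard error.

Defaults: $10^5$ replicates, a validity band of the nominal level
±3 MC-SE, and a null-skewness threshold of 0.1. These are desk-scale
choices that resolve levels down to about $10^{-4}$; direct rejection
counting at $5\times10^{-8}$ would need billions of replicates, so
calibration at genome-wide levels is instead assessed through the
uniformity of the whole null p-value distribution
(Kolmogorov–Smirnov distance) and the skewness of the statistic, whose
far-tail accuracy they govern. A warning is raised whenever the
requested level implies fewer than 5 expected null rejections.

The generator emulates exactly the sampling model the power formulas
assume — independent binomial allele counts under HWE. It does *not*
emulate linkage disequilibrium, imputation uncertainty, covariate
adjustment, population structure, genotyping-platform artefacts, or
control-borrowing biases. Passing calibration here therefore validates
the *asymptotic arithmetic*, not the fitness of any particular set of
real controls; comparability of controls is a prerequisite the package
cannot check. Two robust qualitative findings from the checks: with
10,000 cases, asymptotic p-values are well calibrated even at MAF 1%,
while with 500 cases at MAF 1% the level is visibly off at
$\alpha=10^{-3}$ — and raising $J$ from 1 to 50 does **not** repair it.
When few cases carry a rare allele, more controls are no remedy; exact
methods are.

## Rules of thumb

Two order-of-magnitude shortcuts for the expected p-value, exposed as
advisory helpers and never used inside exact calculations:

* **squaring rule** (`squaring_rule()`): at very many controls per
  case, $p \approx p_{J=1}^2$;
* **doubling rule** (`doubling_rule()`): very many controls at fixed
  cases ≈ doubling the cases at 1:1.

"Very many" is operationalised as $J=1000$, where the OR-reduction
asymptote is attained to 3 significant figures. On a grid of realistic
GWAS designs (5–30k cases, MAF 0.01–0.5, OR 1.05–1.2) with
$p_{J=1}\le10^{-3}$, the doubling rule lands within one decade of the
exact computation and the squaring rule within two; the squaring rule
is the coarser of the pair and degrades as the p-values become extreme.

## Numerical choices

* All tail probabilities are computed in log space
  (`pnorm(..., log.p = TRUE)`), and every p-value is carried with a
  `log10` companion; the p-value channel underflows cleanly to 0 around
  $10^{-320}$ while the log channel stays finite for arbitrarily
  extreme designs. Nothing is truncated.
* Critical deviates are taken from $\alpha$ directly through the upper
  tail (`two_sided_crit_value()`), never by forming $1-\alpha/2$, so no
  precision is lost at small $\alpha$; `z_quantile()` routes
  above-median probabilities through the complement for the same
  reason.
* `min_detectable_or()` root-finds on $\log OR$ (symmetry and
  conditioning), bracketed in $(0, \log 100]$ with absolute tolerance
  $10^{-10}$; power is strictly monotone in $OR>1$, so the root is
  unique, and an unattainable design raises an explicit error rather
  than returning a boundary value.
* `j` is accepted as any real $\ge 1$ — the formulas are continuous —
  while tables default to the conventional grid
  $\{1,2,3,4,5,10,20,50,100,1000\}$.
* MAFs above 0.5 are folded to the minor allele with a warning.
* Printed-precision emulation (`emulate_printed = TRUE`) mirrors how
  compact design tables are typeset: half-up rounding, with the
  2-decimal OR columns rounded *twice* (to 3 decimals, then to 2) —
  the two-stage convention recoverable from such tables' printed cells.
  Comparisons against printed references use half a unit in the last
  printed digit, plus half an intermediate unit where double rounding
  applies.
* Monte-Carlo problem sizes in the shipped tests: $10^5$ replicates
  for calibration and power checks (binomial MC-SE ≈ 0.0007 at
  $\alpha=0.05$), $2\times10^5$ for the rare-allele miscalibration
  check, with fixed seeds throughout; these sizes make the checks exact
  enough to be decisive while keeping the suite fast.

## Known limitations

Non-asymptotic (exact binomial) power is out of scope, as are one-sided
tests, matched or stratified designs, covariate-adjusted
logistic-regression power, genotypic tests, discovery–replication
two-stage designs (winner's curse), and every issue attached to
borrowing real controls — population structure, platform and pipeline
comparability. The local-alternatives results are approximations whose
error grows with the effect size; the explicit allele model is the
fallback whenever $OR_1$ is not small.
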