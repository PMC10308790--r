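# ccpower

Power calculations for case–control association studies that recruit
**many controls per case** and test at **small type-1 error**.

The textbook rule that "more than 4 controls per case buys little power"
is an α = 0.05 result. Large-scale association studies — GWAS,
exome-wide burden tests, -omic and database studies — test thousands to
millions of hypotheses at α between 10⁻⁶ and 10⁻¹², and at those levels
the calculus changes: moving from 4 to 10–50 controls per case can raise
power substantially, drop the expected p-value by orders of magnitude,
and meaningfully shrink the smallest detectable odds ratio. `ccpower`
implements that design arithmetic for epidemiologists and statistical
geneticists planning such studies.

## What it computes

With `J` the controls/case ratio, `α` the two-sided level, `Φ` the
standard normal CDF and `Z_x = Φ⁻¹(x)`:

* **Power transfer across ratios** (local alternatives — everything
  about sample sizes, exposure frequencies and the odds ratio is
  subsumed by the power at J = 1):

  `1−β_J = Φ( Z_{1−β₁} + (Z_{1−β₁} + Z_{1−α/2}) (√(2J/(J+1)) − 1) )`

* **Median expected p-value** of a true association with power 1−β:

  `p = 2 Φ( −| Z_{1−β} + Z_{1−α/2} | )`

  (equals α exactly at 50% power; computed in log space so that
  p-values far below double precision keep a finite log₁₀).

* **Minimum-detectable-OR shrinkage**, depending on the ratio only:

  `(OR₁ − OR_J)/(OR₁ − 1) ≈ 1 − √((J+1)/(2J))`  → 29.3% as J → ∞.

* An **explicit allele-based GWAS power model** (two-proportion test on
  allele counts under Hardy–Weinberg: `n₁ = 2·cases`,
  `n₂ = 2·cases·J`), with the score-test convention (pooled null SD in
  the critical-value term), the Wald convention, and the
  interchanged-SD convention used by established reference tables —
  plus odds-ratio inversion by root finding (`min_detectable_or()`).

* **Monte-Carlo calibration checks** (`validity_report()`): empirical
  type-1 error, power, median p-value and score-statistic skewness from
  simulated 2×2 allele-count tables.

* **Rules of thumb**: at very many controls per case the expected
  p-value is roughly the *square* of its 1:1 value, and roughly what
  *doubling the cases* at 1:1 would achieve.

## Worked example

A genome-wide scan (α = 5×10⁻⁸) has a meagre 20% power for some variant
with 1 control per case. What do more controls buy?

```r
library(ccpower)
power_curve(0.2, 5e-8, j = c(1, 4, 10, 50))
#>    j power median_p log10_median_p
#> 1  1 0.200 4.03e-06          -5.39
#> 2  4 0.648 5.51e-09          -8.26
#> 3 10 0.778 5.11e-10          -9.29
#> 4 50 0.842 1.08e-10          -9.97
```

Power climbs 0.20 → 0.65 → 0.78 → 0.84, and the p-value one should
expect for the association falls from 4×10⁻⁶ (above genome-wide
significance) to 1×10⁻¹⁰ — nearly four orders of magnitude, most of it
*after* the classical 4:1 design.

The OR side of the same story, regardless of α:

```r
table_min_or_by_ratio(emulate_printed = TRUE)[c(1, 4, 8), c(1, 5, 8:10)]
#>    j or_1.3 or_2 pct_reduction_vs_j1 pct_reduction_vs_j4
#> 1  1   1.30 2.00                 0.0               -26.5
#> 4  4   1.24 1.79                20.9                 0.0
#> 8 50   1.21 1.71                28.6                 9.7
```

An OR of 2 detectable at 1:1 becomes detectable at 1.79 with 4 controls
per case (20.9% of the way to the null) and 1.71 with 50 (a further
9.7%).

And for a concrete GWAS design — 10,000 cases, 4 controls each, a
common allele (MAF 0.5) carrying OR 1.1:

```r
d <- allele_design(10000, 4, maf_controls = 0.5, odds_ratio = 1.1)
score_test_power(d)        # 0.717
expected_pvalue_gwas(d)    # median p = 1.7e-9
```

A command-line interface with subcommands (`power`, `gwas-min-or`,
`table1`, `table2`, `simulate`, `rules`, ...) is installed at
`system.file("cli", "ccpower", package = "ccpower")`.

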