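# Reference design tables and machine-readable grids: minimum detectable
# ORs by controls/case ratio, GWAS minimum detectable ORs, and the
# power / expected-p-value grids behind the standard design figures.

default_j_grid <- c(1, 2, 3, 4, 5, 10, 20, 50, 100, 1000)
default_alpha_grid <- c(0.05, 1e-3, 2.5e-6, 5e-8, 5e-9, 3e-12)

# round-half-up at d decimals (display convention of compact design
# tables; base round() is round-half-even)
round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d

#' Minimum detectable OR by controls/case ratio (ratio-only table)
#'
#' Tabulates [min_detectable_or_at_ratio()] over a grid of 1:1 minimum
#' detectable ORs and controls/case ratios, with the percent reduction
#' toward the null versus 1 control/case and versus a 4:1 baseline.  The
#' table depends only on the ratio, so it applies to any \eqn{\alpha},
#' power, marker frequency and sample size that yield the 1:1 OR.
#'
#' With `emulate_printed = TRUE` the ORs are rounded the way compact
#' design tables print them: half-up to 3 decimals for base ORs up to
#' 1.1; for larger base ORs half-up to 3 decimals and then again to 2
#' (the two-stage rounding such tables were typeset with); percent
#' columns half-up to 1 decimal.
#'
#' @param or_j1 Grid of minimum detectable ORs at 1 control/case.
#' @param j Grid of controls/case ratios.
#' @param j_baseline Baseline ratio for the incremental percent column.
#' @param emulate_printed Round to table-display precision (default
#'   `FALSE`: full double precision).
#' @return A data frame in wide layout: one row per `j`, one OR column per
#'   `or_j1` (named `or_<value>`), plus `pct_reduction_vs_j1` and
#'   `pct_reduction_vs_j4`.
#' @examples
#' table_min_or_by_ratio(emulate_printed = TRUE)
#' @export
table_min_or_by_ratio <- function(or_j1 = c(1.05, 1.1, 1.2, 1.3, 1.5, 1.75, 2),
                                  j = default_j_grid,
                                  j_baseline = 4,
                                  emulate_printed = FALSE) {
  cols <- lapply(or_j1, function(o) {
    or_j <- min_detectable_or_at_ratio(o, j, j_baseline)$or_j
    if (emulate_printed) {
      or_j <- round_half_up(or_j, 3)
      if (o > 1.1) or_j <- round_half_up(or_j, 2)
    }
    or_j
  })
  names(cols) <- paste0("or_", or_j1)
  frac1 <- 100 * or_reduction_fraction(j)
  fracb <- 100 * (or_reduction_fraction(j) - or_reduction_fraction(j_baseline)) /
    (1 - or_reduction_fraction(j_baseline))
  if (emulate_printed) {
    frac1 <- round_half_up(frac1, 1)
    fracb <- round_half_up(fracb, 1)
  }
  out <- data.frame(j = j, cols,
                    pct_reduction_vs_j1 = frac1,
                    pct_reduction_vs_j4 = fracb,
                    check.names = FALSE)
  names(out)[ncol(out)] <- sprintf("pct_reduction_vs_j%g", j_baseline)
  out
}

#' Minimum detectable OR table for GWAS designs
#'
#' Tabulates [min_detectable_or()] over grids of case counts,
#' controls/case ratios and control minor allele frequencies, at a fixed
#' target power and significance level.  Each cell is obtained by root
#' finding on the allele-based power model.
#'
#' The default `method = "swapped"` is the interchanged-SD convention
#' that established reference tables of this kind were computed with, so
#' the generated table matches them cell for cell; pass
#' `method = "score"` for the simulation-validated score-test power
#' (which detects somewhat smaller ORs at rare MAF in unbalanced
#' designs).  See [min_detectable_or()] for the distinction.
#'
#' With `emulate_printed = TRUE` cells are rounded to 2 decimals, or 3
#' where the OR is within 0.1 of the null (compact-table convention).
#'
#' @param n_cases Grid of case counts.
#' @param j Grid of controls/case ratios.
#' @param maf Grid of control minor allele frequencies.
#' @param alpha Two-sided type-1 error (default genome-wide `5e-8`).
#' @param target_power Power each cell attains (default 0.8).
#' @param method Power convention passed to [min_detectable_or()].
#' @param emulate_printed Round to table-display precision.
#' @return A long-format data frame: `n_cases`, `j`, `maf`, `min_or`.
#' @examples
#' table_min_or_gwas(n_cases = 10000, j = c(1, 50), maf = c(0.01, 0.5))
#' @export
table_min_or_gwas <- function(n_cases = c(2500, 5000, 10000, 20000, 40000,
                                          80000, 160000, 320000),
                              j = c(1, 4, 10, 50),
                              maf = c(0.01, 0.05, 0.1, 0.2, 0.5),
                              alpha = 5e-8, target_power = 0.8,
                              method = c("swapped", "score", "wald"),
                              emulate_printed = FALSE) {
  method <- match.arg(method)
  grid <- expand.grid(maf = maf, j = j, n_cases = n_cases,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[c("n_cases", "j", "maf")]
  grid$min_or <- mapply(function(n, jj, m) {
    min_detectable_or(n, jj, m, alpha = alpha, target_power = target_power,
                      method = method)
  }, grid$n_cases, grid$j, grid$maf)
  if (emulate_printed) {
    grid$min_or <- ifelse(round(grid$min_or, 3) < 1.1,
                          round(grid$min_or, 3), round(grid$min_or, 2))
  }
  rownames(grid) <- NULL
  grid
}

#' Power and expected-p-value grids across ratios and significance levels
#'
#' `power_grid()` evaluates the ratio-only power transfer and median
#' expected p-value over a full factorial of baseline powers, significance
#' levels and controls/case ratios -- the long-format data behind the
#' standard power-versus-ratio design curves.  `pvalue_grid()` is the
#' simpler power-by-alpha lookup of median expected p-values (no ratio
#' dimension): what p-value to expect from an association with a given
#' power at a given level.
#'
#' @param power_j1 Baseline powers at 1 control/case.
#' @param alpha Two-sided significance levels.
#' @param j Controls/case ratios.
#' @return `power_grid()`: data frame `power_j1`, `alpha`, `j`, `power`,
#'   `median_p`, `log10_median_p`.  `pvalue_grid()`: data frame `power`,
#'   `alpha`, `median_p`, `log10_median_p`.
#' @examples
#' head(power_grid(power_j1 = 0.2, alpha = 5e-8))
#' pvalue_grid(power = c(0.5, 0.8), alpha = c(0.05, 5e-8))
#' @export
power_grid <- function(power_j1 = c(0.1, 0.2, 0.3, 0.5),
                       alpha = default_alpha_grid,
                       j = default_j_grid) {
  grid <- expand.grid(j = j, alpha = alpha, power_j1 = power_j1,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[c("power_j1", "alpha", "j")]
  grid$power <- power_at_ratio(grid$power_j1, grid$alpha, grid$j)
  grid$log10_median_p <- median_p_log10(grid$power, grid$alpha)
  grid$median_p <- 10^grid$log10_median_p
  rownames(grid) <- NULL
  grid[c("power_j1", "alpha", "j", "power", "median_p", "log10_median_p")]
}

#' @rdname power_grid
#' @param power Powers for the direct power-by-alpha lookup.
#' @export
pvalue_grid <- function(power = c(0.1, 0.2, 0.3, 0.5, 0.8, 0.9),
                        alpha = default_alpha_grid) {
  grid <- expand.grid(alpha = alpha, power = power, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[c("power", "alpha")]
  grid$log10_median_p <- median_p_log10(grid$power, grid$alpha)
  grid$median_p <- 10^grid$log10_median_p
  rownames(grid) <- NULL
  grid
}

#' Write a results table to CSV and/or JSON
#'
#' Writes a data frame produced by the table/grid generators to disk in
#' machine-readable form.  CSV is RFC-4180 (quoted strings, `.` decimal);
#' JSON is an array of records written at full double precision, so both
#' formats round-trip through [read_report()] without loss beyond the
#' 15-significant-digit CSV representation.
#'
#' @param x A data frame.
#' @param path Output path without extension; `.csv` / `.json` appended.
#' @param formats Subset of `c("csv", "json")`.
#' @return Invisibly, the character vector of files written.
#' @export
write_report <- function(x, path, formats = c("csv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  written <- character(0)
  if ("csv" %in% formats) {
    f <- paste0(path, ".csv")
    utils::write.csv(format(x, digits = 15, scientific = NA, trim = TRUE),
                     f, row.names = FALSE, quote = TRUE)
    written <- c(written, f)
  }
  if ("json" %in% formats) {
    f <- paste0(path, ".json")
    jsonlite::write_json(x, f, dataframe = "rows", digits = NA,
                         na = "null")
    written <- c(written, f)
  }
  invisible(written)
}

#' @rdname write_report
#' @param file A file previously written by [write_report()].
#' @export
read_report <- function(file) {
  if (grepl("\\.json$", file)) {
    as.data.frame(jsonlite::read_json(file, simplifyVector = TRUE))
  } else {
    utils::read.csv(file)
  }
}
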