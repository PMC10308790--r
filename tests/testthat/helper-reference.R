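# Reference printed design tables, stored as strings so the printed
# decimal width (and hence the half-unit tolerance) is recoverable.

ref_table_ratio <- function() {
  utils::read.csv(system.file("extdata", "reference_min_or_by_ratio.csv",
                              package = "ccpower"),
                  colClasses = "character", check.names = FALSE)
}

ref_table_gwas <- function() {
  utils::read.csv(system.file("extdata", "reference_min_or_gwas.csv",
                              package = "ccpower"),
                  colClasses = "character")
}

# half a unit in the last printed digit, from the printed string
half_printed_unit <- function(s) {
  0.5 * 10^(-nchar(sub("^[^.]*[.]?", "", s)))
}

# absolute-tolerance comparison: "agrees with the printed value to half
# a unit in its last digit" (testthat's expect_equal tolerance is
# relative, which is the wrong scale for tiny p-values)
expect_near <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}

# grids the ratio-only formulas are asserted over
grid_j <- c(1, 2, 4, 10, 20, 50, 100)
grid_alpha <- c(0.05, 1e-3, 2.5e-6, 5e-8, 5e-9, 3e-12)
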