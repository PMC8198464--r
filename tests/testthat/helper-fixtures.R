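# Shared fixtures, all built in code at test time.

# analytic isotherms for derivative oracles
linear_isotherm <- function(m = 5, A0 = 2, n = 100) {
  a <- seq(1.8, 0.2, length.out = n)
  isotherm(a, m * (A0 - a), label = "linear")
}

ideal_gas_isotherm <- function(c = 10, n = 200) {
  a <- seq(2, 0.5, length.out = n)
  isotherm(a, c / a, label = "ideal-gas")
}

# write a small isotherm CSV and return its path
write_iso_csv <- function(df, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  path
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_true(all(abs(object - expected) <= rel_tol * abs(expected)),
              label = sprintf("%s within %g relative of %s",
                              paste(signif(object, 8), collapse = ", "),
                              rel_tol,
                              paste(signif(expected, 8), collapse = ", ")))
}
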