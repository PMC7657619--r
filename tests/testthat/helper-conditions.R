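# Packaged reference conditions, loaded once per test run.
ct_condition <- function() {
  read_condition(ppiflux_example("chemostat_cthermocellum.tsv"))
}

ts_condition <- function() {
  read_condition(ppiflux_example("chemostat_tsaccharolyticum.tsv"))
}

# Reaction equality: same species set with identical rational coefficients.
expect_same_reaction <- function(object, expected) {
  o <- tidy(object)
  e <- tidy(expected)
  o <- o[order(o$species), ]
  e <- e[order(e$species), ]
  expect_equal(o$species, e$species)
  expect_identical(o$numerator, e$numerator)
  expect_identical(o$denominator, e$denominator)
}
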