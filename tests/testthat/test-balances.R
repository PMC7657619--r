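test_that("CO2 is inferred from fermentation stoichiometry for both organisms", {
  expect_equal(infer_co2(ct_condition()), 1254.0, tolerance = 0.5 / 1254)
  expect_equal(infer_co2(ts_condition()), 1815.9, tolerance = 0.5 / 1254)

  # all-zero condition infers zero
  empty <- chemostat_condition(dilution_rate = 0.1)
  expect_identical(infer_co2(empty), 0)

  # formate in excess of decarboxylations is a balance inconsistency
  bad <- chemostat_condition(dilution_rate = 0.1,
                             products = c(acetate = 10, ethanol = 0,
                                          formate = 500, isobutanol = 0))
  expect_error(infer_co2(bad), "negative")
})

test_that("infer_co2 is linear in each product concentration", {
  base <- c(acetate = 500, ethanol = 300, formate = 100, isobutanol = 20)
  co2_at <- function(products) {
    infer_co2(chemostat_condition(dilution_rate = 0.1, products = products))
  }
  f0 <- co2_at(base)
  for (sp in names(base)) {
    up <- base; up[sp] <- 2 * base[sp]
    delta <- co2_at(up) - f0
    up2 <- base; up2[sp] <- 3 * base[sp]
    expect_equal(co2_at(up2) - f0, 2 * delta, tolerance = 1e-12)
  }
})

test_that("the valine-inclusive CO2 variant adds exactly one CO2 per valine", {
  ct <- ct_condition()
  with_val <- infer_co2(ct, include_valine = TRUE)
  without <- infer_co2(ct, include_valine = FALSE)
  valine_mmol <- to_mmol(15.0, "valine", "anion")
  expect_equal(with_val - without, valine_mmol * 44.009, tolerance = 1e-6)
})

test_that("carbon recovery closes to the published balances with anion masses", {
  rep_ct <- carbon_recovery(ct_condition())
  expect_equal(rep_ct$carbon_recovery, 84.0, tolerance = 0.1 / 84)
  rep_ts <- carbon_recovery(ts_condition())
  expect_equal(rep_ts$carbon_recovery, 88.8, tolerance = 0.1 / 88)

  # component table is nonnegative and sums to out/in consistency
  expect_true(all(tidy(rep_ct)$carbon >= 0))
  expect_equal(100 * sum(tidy(rep_ct)$carbon) / rep_ct$carbon_in,
               rep_ct$carbon_recovery)
  expect_equal(glance(rep_ct)$carbon_recovery, rep_ct$carbon_recovery)
})

test_that("recovery is invariant to splitting a product across duplicate rows", {
  ct <- ct_condition()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_condition(ct, path)
  lines <- readLines(path)
  i <- grep("^acetate\t", lines)
  conc <- as.numeric(strsplit(lines[i], "\t")[[1]][2])
  lines[i] <- paste("acetate", conc / 3, "product", sep = "\t")
  lines <- append(lines, paste("acetate", 2 * conc / 3, "product", sep = "\t"),
                  after = i)
  writeLines(lines, path)
  split_cond <- read_condition(path)
  expect_equal(carbon_recovery(split_cond)$carbon_recovery,
               carbon_recovery(ct)$carbon_recovery, tolerance = 1e-12)
})

test_that("nitrogen recovery accounts cells, amino acids and protein against feed N", {
  # all feed N routed to cells
  cond <- chemostat_condition(dilution_rate = 0.1, cell_nitrogen = 100,
                              cell_carbon = 331, feed_nitrogen = 100)
  expect_equal(nitrogen_recovery(cond), 100)

  # cells hold half the feed N, nothing else
  cond2 <- chemostat_condition(dilution_rate = 0.1, cell_nitrogen = 50,
                               cell_carbon = 165, feed_nitrogen = 100)
  expect_equal(nitrogen_recovery(cond2), 50)

  # reference condition: recovery equals the three sinks over feed N
  ct <- ct_condition()
  expected <- 100 * (102.0 + 20.6 + 103.5 * 0.161) / ct$feed_nitrogen
  expect_equal(nitrogen_recovery(ct), expected, tolerance = 1e-12)

  expect_error(
    nitrogen_recovery(chemostat_condition(dilution_rate = 0.1,
                                          cell_nitrogen = 10,
                                          cell_carbon = 33)),
    "feed_nitrogen"
  )
})

test_that("cellular C/N ratio is carbon over nitrogen", {
  expect_equal(cn_ratio(ct_condition()), 3.31, tolerance = 0.01 / 3.31)
  sym <- chemostat_condition(dilution_rate = 0.1, cell_carbon = 77,
                             cell_nitrogen = 77)
  expect_identical(cn_ratio(sym), 1)
  expect_error(cn_ratio(chemostat_condition(dilution_rate = 0.1,
                                            cell_carbon = 1,
                                            cell_nitrogen = 0)), "positive")
})

test_that("a multi-level synthetic series recovers the generator C/N ratio by regression", {
  # emulate a substrate-gradient series: same flux proportions, increasing
  # biomass, fixed cellular C/N of 3.34 g/g
  levels <- seq(0.25, 1, by = 0.25)
  pts <- purrr::map_dfr(levels, function(s) {
    spec <- generator_spec(cell_nitrogen = 102 * s, cell_cn_ratio = 3.34,
                           noise_cv = 0.01, seed = 7 + round(100 * s))
    cond <- generate_conditions(spec)$conditions[[1]]
    tibble::tibble(cell_n = cond$cell_nitrogen, cell_c = cond$cell_carbon)
  })
  fit <- stats::lm(cell_c ~ 0 + cell_n, data = pts)
  expect_equal(unname(stats::coef(fit)[1]), 3.34, tolerance = 1e-6)
})
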