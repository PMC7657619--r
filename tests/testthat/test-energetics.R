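test_that("anabolic PPi sources sum to the 11 mmol/g cells budget", {
  expect_equal(anabolic_ppi_total(), 10.97)
  expect_equal(anabolic_ppi_total(c(protein = 7.67)), 7.67)
  expect_identical(anabolic_ppi_total(numeric()), 0)
  expect_error(anabolic_ppi_total(c(protein = -1)), ">= 0")
})

test_that("cellobiose partition splits total consumption into anabolic and catabolic", {
  part <- cellobiose_partition(0.16, 3.7, 0.16)
  expect_equal(part$total, 18.2, tolerance = 0.1 / 18.2)
  expect_equal(part$catabolic, 11.6, tolerance = 0.05 / 11.6)
  expect_equal(part$total - part$anabolic - part$unaccounted, part$catabolic)

  # with no anabolic or unaccounted share, everything is catabolic
  all_cat <- cellobiose_partition(0.16, 0, 0)
  expect_equal(all_cat$catabolic, all_cat$total)

  # the unaccounted fraction is 1 - recovery/100 of the closed balance
  recovery <- carbon_recovery(ct_condition())$carbon_recovery
  expect_equal(1 - recovery / 100, 0.16, tolerance = 0.001 / 0.16)

  expect_error(cellobiose_partition(0.16, 30, 0.16), "negative")
})

test_that("catabolic PPi demand reproduces the published budget at the PPDK fraction 2/3", {
  bud <- catabolic_ppi_demand(cellobiose_partition(), 2 / 3)
  expect_equal(bud$catabolic_pfk, 23.2, tolerance = 0.01)
  expect_equal(bud$catabolic_ppdk, 30.9, tolerance = 0.01)
  expect_equal(bud$catabolic_total, 54.1, tolerance = 0.01)
  expect_equal(bud$catabolic_total, bud$catabolic_pfk + bud$catabolic_ppdk)

  part <- cellobiose_partition()
  none <- catabolic_ppi_demand(part, 0)
  expect_equal(none$catabolic_total, none$catabolic_pfk)
  expect_equal(none$catabolic_ppdk, 0)
  full <- catabolic_ppi_demand(part, 1)
  expect_equal(full$catabolic_ppdk, 4 * part$catabolic)

  # monotone nondecreasing in the PPDK fraction, linear in catabolic cellobiose
  fracs <- seq(0, 1, by = 0.1)
  totals <- vapply(fracs, function(f) {
    catabolic_ppi_demand(part, f)$catabolic_total
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  half <- cellobiose_partition(0.16, part$anabolic + part$catabolic / 2, 0.16)
  expect_equal(catabolic_ppi_demand(half, 0.5)$catabolic_total,
               catabolic_ppi_demand(part, 0.5)$catabolic_total / 2,
               tolerance = 1e-12)
})

test_that("anabolic supply falls far short of catabolic demand at the defaults", {
  bud <- catabolic_ppi_demand(cellobiose_partition())
  expect_lt(bud$anabolic_total, bud$catabolic_total)
  expect_equal(bud$anabolic_total, 10.97)
  expect_gt(bud$catabolic_total, 54)
  g <- glance(bud)
  expect_gt(g$shortfall, 43)
})

test_that("the PPi credit lowers the ATP requirement and raises Y_ATPmax", {
  acc <- atp_requirement_with_ppi_credit(34.7, 11)
  expect_equal(acc$adjusted_requirement, 23.7)
  expect_equal(acc$y_atp_max, 42.2, tolerance = 0.05 / 42.2)
  expect_equal(acc$y_atp_base, 28.8, tolerance = 0.05 / 28.8)

  no_credit <- atp_requirement_with_ppi_credit(34.7, 0)
  expect_equal(no_credit$y_atp_max, no_credit$y_atp_base)

  # halving the requirement doubles the maximum yield, and the identity
  # y_atp_max * adjusted = 1000 holds exactly
  for (base in c(20, 34.7, 60)) {
    acc2 <- atp_requirement_with_ppi_credit(base, base / 2)
    expect_equal(acc2$y_atp_max, 2 * acc2$y_atp_base)
    expect_equal(acc2$y_atp_max * acc2$adjusted_requirement, 1000)
  }
  expect_error(atp_requirement_with_ppi_credit(34.7, 40), "smaller")
})

test_that("protein synthesis saving is one ATP per residue, 14% of the requirement", {
  expect_equal(protein_residues_mmol(), 4.8, tolerance = 0.05 / 4.8)
  expect_equal(protein_atp_saving(), 14)
  expect_equal(protein_atp_saving(protein_fraction = 0), 0)
})

test_that("the lysis hypothesis implies implausible cell masses and concentrations", {
  expect_equal(round(lysis_required_cell_mass(100, 0.6)), 167)
  expect_equal(lysis_required_cell_mass(100, 1.0), 100)
  expect_identical(lysis_required_cell_mass(0, 0.6), 0)

  expect_equal(lysis_implied_concentration(100, 111, 0.6, 2.0), 2.7,
               tolerance = 0.01)
  # intensive in the amino acid amount, inversely scaling with cell volume
  expect_equal(lysis_implied_concentration(50, 111, 0.6, 2.0),
               lysis_implied_concentration(100, 111, 0.6, 2.0))
  expect_equal(lysis_implied_concentration(100, 111, 0.6, 4.0),
               lysis_implied_concentration(100, 111, 0.6, 2.0) / 2)
})
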