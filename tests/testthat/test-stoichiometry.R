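test_that("reaction parsing handles coefficients, rationals and merging", {
  r <- parse_reaction("PEP + AMP + PPi -> pyruvate + ATP + Pi")
  expect_s3_class(r, "reaction")
  expect_length(r$species, 6)
  expect_setequal(r$species[r$num < 0], c("PEP", "AMP", "PPi"))
  expect_setequal(r$species[r$num > 0], c("pyruvate", "ATP", "Pi"))

  ak <- parse_reaction("2 ADP -> AMP + ATP")
  expect_equal(ak$num[ak$species == "ADP"], -2)

  half <- parse_reaction("1/2 glucose + ATP -> G6P")
  expect_equal(half$num[half$species == "glucose"], -1)
  expect_equal(half$den[half$species == "glucose"], 2)

  # same species both sides nets out; an empty net is rejected
  net <- parse_reaction("A + B -> 2 A + C")
  expect_equal(net$num[net$species == "A"], 1)
  expect_error(parse_reaction("A -> A"), "consumed and one produced")
  expect_error(parse_reaction("A + B -> "), "Empty|Malformed")
  expect_error(parse_reaction("A B C"), "arrow")

  # aliases canonicalise to one spelling
  al <- parse_reaction("ATP + P_i -> ADP + PP_i")
  expect_setequal(al$species, c("ATP", "Pi", "ADP", "PPi"))

  rev <- parse_reaction("A <-> B")
  expect_true(rev$reversible)
})

test_that("combine cancels intermediates with exact rational arithmetic", {
  p <- canned_pathways()

  # PPDK + adenylate kinase: the classical 2-ATP summation
  expect_same_reaction(
    combine(p$ppdk_classical),
    parse_reaction("PEP + 2 ADP + PPi -> pyruvate + 2 ATP + Pi"))

  # with the PPi-generating mechanism the net collapses to pyruvate kinase
  expect_same_reaction(combine(p$ppdk_in_vivo),
                       parse_reaction("PEP + ADP -> pyruvate + ATP"))

  # six pentose reactions sum to the transaldolase-free net (with its Pi)
  expect_same_reaction(
    combine(p$pentose_no_transaldolase),
    parse_reaction("3 F6P + PPi -> 3 C5P + C3P + Pi"))

  # rational multipliers: a third of the pentose net scales exactly
  scaled <- combine(pathway_combination(
    list(combine(p$pentose_no_transaldolase)), multipliers = "1/3"))
  expect_equal(scaled$num[scaled$species == "F6P"], -1)
  expect_equal(scaled$den[scaled$species == "PPi"], 3)
})

test_that("combine is linear under scaling of the whole combination", {
  p <- canned_pathways()
  base <- combine(p$malate_shunt)
  for (k in c(2, 3, 7)) {
    scaled <- combine(pathway_combination(p$malate_shunt$reactions,
                                          multipliers = rep(k, 3)))
    expect_setequal(scaled$species, base$species)
    i <- match(base$species, scaled$species)
    expect_equal(scaled$num[i] / scaled$den[i],
                 k * base$num / base$den, tolerance = 1e-15)
  }
})

test_that("the canned library reproduces every printed pathway net", {
  p <- canned_pathways()

  expect_same_reaction(
    combine(p$trna_charging_ecoli),
    parse_reaction("aa1 + aa2 + 2 GTP + 2 ATP -> aa1-aa2 + 2 GDP + 2 ADP + 4 Pi"))

  expect_same_reaction(
    combine(p$malate_shunt),
    parse_reaction("PEP + GDP + NADH + NADP -> pyruvate + GTP + NAD + NADPH"))

  expect_same_reaction(p$glycogen_cycle_net,
                       parse_reaction("ATP + Pi -> ADP + PPi"))

  expect_same_reaction(
    p$nfnab,
    parse_reaction("ferredoxinred + NADH + 2 NADP -> ferredoxinox + NAD + 2 NADPH"))

  # lacking a soluble pyrophosphatase, recycling PPi through PPDK saves one
  # ATP equivalent per peptide bond (PEP counted at 1 ATP equivalent)
  cost_ecoli <- atp_equivalents(combine(p$trna_charging_ecoli))
  cost_no_ppase <- atp_equivalents(combine(p$trna_charging_no_ppase))
  expect_equal(cost_ecoli, 4)
  expect_equal(cost_no_ppase, 3)
  expect_equal(cost_ecoli - cost_no_ppase, 1)
})

test_that("phosphate ledger verifies balance of canned nets and flags the printed typos", {
  p <- canned_pathways()
  balanced <- list(
    p$pp_glycolysis_net, p$ppdk, p$adenylate_kinase, p$ppi_generator,
    combine(p$ppdk_classical), combine(p$ppdk_in_vivo),
    combine(p$malate_shunt), p$nfnab, combine(p$trna_charging_ecoli),
    combine(p$pentose_no_transaldolase), p$glycogen_cycle_net
  )
  for (rx in balanced) {
    bal <- suppressWarnings(element_balance(rx, quiet = TRUE))
    expect_equal(unname(bal["P"]), 0, tolerance = 1e-12)
  }

  # the two as-printed variants are deliberately phosphate-unbalanced
  printed <- as_printed_variants()
  expect_setequal(printed, c("ppdk_in_vivo_as_printed", "pentose_net_as_printed"))
  pent <- element_balance(p$pentose_net_as_printed, quiet = TRUE)
  expect_equal(unname(pent["P"]), -1)
  ppdk_printed <- element_balance(p$ppdk_in_vivo_as_printed, quiet = TRUE)
  expect_equal(unname(ppdk_printed["P"]), -3)
})

test_that("element balance nets formula elements and warns on unknown species", {
  # full-formula reaction balances every element exactly
  resp <- parse_reaction("glucose + 6 O2 -> 6 CO2 + 6 H2O")
  reg <- compound_registry(extra = tibble::tibble(name = "O2", formula = "O2"))
  bal <- element_balance(resp, registry = reg, quiet = TRUE)
  expect_equal(unname(bal[c("C", "H", "O")]), c(0, 0, 0))

  expect_warning(
    element_balance(parse_reaction("mystery -> glucose")),
    "skipped"
  )
})

test_that("net ATP per glucose follows the glycolytic stoichiometry", {
  expect_equal(net_atp_per_glucose(0.5), 3.5)
  expect_equal(net_atp_per_glucose(1), 2)
  expect_equal(net_atp_per_glucose(0), 5)
  expect_error(net_atp_per_glucose(-1))
})
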