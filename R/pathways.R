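#' Built-in library of reactions and pathway combinations
#'
#' The symbolic reaction set behind pyrophosphate-dependent glycolysis and
#' its bioenergetics: the glycolytic net, PPDK and adenylate kinase with the
#' PPi-generating mechanism and their in-vivo net, the malate shunt, the
#' NfnAB transhydrogenase, tRNA-charging nets with and without a soluble
#' pyrophosphatase, the transaldolase-free pentose phosphate cycle, and the
#' glycogen cycle net. Water is treated as implicit (omitted from equations),
#' matching the convention of the source equations.
#'
#' Two published equations are phosphate-unbalanced as printed (the pentose
#' net omits a product Pi; the in-vivo PPDK line omits product ATP); both are
#' kept verbatim as `*_as_printed` entries so the discrepancy stays visible,
#' alongside the corrected forms the combinations actually produce.
#'
#' @return A named list. Elements are [reaction()] or
#'   [pathway_combination()] objects; combinations are summed with
#'   [combine()].
#' @examples
#' p <- canned_pathways()
#' combine(p$ppdk_in_vivo) # PEP + ADP -> pyruvate + ATP
#' @export
canned_pathways <- function() {
  rx <- function(text, name) parse_reaction(text, name = name)

  ppdk <- rx("PEP + AMP + PPi -> pyruvate + ATP + Pi", "ppdk")
  ak <- rx("2 ADP -> AMP + ATP", "adenylate_kinase")
  ppi_gen <- rx("ATP + Pi -> ADP + PPi", "ppi_generator")

  pepck <- rx("PEP + CO2 + GDP -> OAA + GTP", "pep_carboxykinase")
  mdh <- rx("OAA + NADH -> malate + NAD", "malate_dehydrogenase")
  me <- rx("malate + NADP -> pyruvate + CO2 + NADPH", "malic_enzyme")

  # tRNA charging + peptide-bond formation, E. coli style: the PPi released
  # by aminoacyl-tRNA synthetase is hydrolysed by the soluble pyrophosphatase
  # (water implicit), costing a second ATP equivalent per bond.
  charging <- rx(
    "aa1 + aa2 + 2 GTP + ATP -> aa1-aa2 + 2 GDP + 2 Pi + AMP + PPi",
    "trna_charging_and_bond"
  )
  ppase <- rx("PPi -> 2 Pi", "soluble_pyrophosphatase")
  ak_rev <- rx("AMP + ATP -> 2 ADP", "adenylate_kinase_reverse")

  pentose <- list(
    rx("2 F6P + 2 PPi -> 2 FBP + 2 Pi", "ppi_pfk"),
    rx("2 FBP -> 4 C3P", "aldolase_fbp"),
    rx("F6P + C3P -> C5P + C4P", "transketolase_1"),
    rx("C4P + C3P -> SBP", "aldolase_sbp"),
    rx("SBP + Pi -> C7P + PPi", "ppi_pfk_sbp"),
    rx("C7P + C3P -> 2 C5P", "transketolase_2")
  )

  list(
    pp_glycolysis_net = rx(
      "glucose + 5 ADP + 3 PPi -> 2 pyruvate + 5 ATP + Pi",
      "pp_glycolysis_net"
    ),
    ppdk = ppdk,
    adenylate_kinase = ak,
    ppi_generator = ppi_gen,
    ppdk_classical = pathway_combination(list(ppdk, ak),
                                         name = "ppdk_classical"),
    ppdk_in_vivo = pathway_combination(list(ppdk, ppi_gen, ak),
                                       name = "ppdk_in_vivo"),
    ppdk_in_vivo_as_printed = rx("PEP + AMP + PPi -> pyruvate + Pi",
                                 "ppdk_in_vivo_as_printed"),
    pep_carboxykinase = pepck,
    malate_dehydrogenase = mdh,
    malic_enzyme = me,
    malate_shunt = pathway_combination(list(pepck, mdh, me),
                                       name = "malate_shunt"),
    nfnab = rx(
      "ferredoxinred + NADH + 2 NADP -> ferredoxinox + NAD + 2 NADPH",
      "nfnab"
    ),
    trna_charging_and_bond = charging,
    soluble_pyrophosphatase = ppase,
    trna_charging_ecoli = pathway_combination(
      list(charging, ppase, ak_rev), name = "trna_charging_ecoli"
    ),
    # without a soluble pyrophosphatase the AMP + PPi pair is recycled by
    # PPDK, saving one ATP equivalent per peptide bond
    trna_charging_no_ppase = pathway_combination(
      list(charging, ppdk), name = "trna_charging_no_ppase"
    ),
    pentose_no_transaldolase = pathway_combination(
      pentose, name = "pentose_no_transaldolase"
    ),
    pentose_net_as_printed = rx("3 C6P + PPi -> 3 C5P + C3P",
                                "pentose_net_as_printed"),
    glycogen_cycle_net = rx("ATP + Pi -> ADP + PPi", "glycogen_cycle_net")
  )
}

#' Flagged as-printed pathway variants
#'
#' Names of library entries kept verbatim from their published form although
#' phosphate-unbalanced (apparent typographical omissions); their corrected
#' counterparts are produced by the corresponding combinations.
#'
#' @return Character vector of entry names.
#' @export
as_printed_variants <- function() {
  c("ppdk_in_vivo_as_printed", "pentose_net_as_printed")
}
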