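# Bioenergetic defaults: every constant of the pyrophosphate budget in one
# overridable place (none is hard-wired into a formula).
#   - anabolic PPi per g cells by macromolecule class (E. coli network
#     accounting: protein, RNA+DNA, lipids+LPS, glycogen)
#   - anabolic cellobiose demand and biomass yield of the carbon-limited
#     reference culture
#   - Stouthamer-style ATP requirement for biosynthesis and protein content

#' Default bioenergetic constants
#'
#' @return A list with the default anabolic PPi sources (mmol/g cells),
#'   anabolic cellobiose (mmol/g cells), biomass yield (g cells/g
#'   cellobiose), unaccounted-carbon fraction, PPDK flux fraction, cell
#'   carbon fraction (g C/g cells), cellobiose molar mass (g/mmol), base ATP
#'   requirement (mmol/g cells), protein mass fraction and mean residue mass
#'   (g/mol).
#' @export
energetics_defaults <- function() {
  list(
    anabolic_ppi_sources = c(protein = 7.67, nucleic_acids = 1.16,
                             lipids_lps = 2.11, glycogen = 0.03),
    anabolic_cellobiose = 3.7,
    biomass_yield = 0.16,
    unaccounted_fraction = 0.16,
    ppdk_fraction = 2 / 3,
    carbon_fraction = 0.45,
    cellobiose_g_per_mmol = 0.3423,
    base_atp_requirement = 34.7,
    protein_fraction = 0.524,
    residue_mass = 110
  )
}

#' Total anabolic pyrophosphate generated per gram of cells
#'
#' Polymerisation of monomers (amino acid, nucleotide, lipid and glycogen
#' units) releases PPi; this sums the per-macromolecule contributions.
#'
#' @param sources Named nonnegative vector, mmol PPi/g cells per
#'   macromolecule class.
#' @return mmol PPi per g cells.
#' @examples
#' anabolic_ppi_total() # 10.97, reported as 11
#' @export
anabolic_ppi_total <- function(sources = energetics_defaults()$anabolic_ppi_sources) {
  if (any(sources < 0)) stop("PPi sources must be >= 0", call. = FALSE)
  sum(sources)
}

#' Partition cellobiose consumption into anabolic and catabolic use
#'
#' Total cellobiose per gram of cells is the inverse of the biomass yield in
#' molar units; subtracting the anabolic requirement and the unaccounted
#' (missing-carbon) share leaves the catabolic cellobiose that must be
#' fermented for ATP.
#'
#' @param biomass_yield g cells per g cellobiose.
#' @param anabolic mmol cellobiose per g cells used in biosynthesis.
#' @param unaccounted_fraction Fraction of cellobiose unaccounted for in the
#'   carbon balance, typically `1 - recovery/100`; in `[0, 1)`.
#' @param cellobiose_g_per_mmol Molar mass in g/mmol.
#' @return A list of class `cellobiose_partition`.
#' @examples
#' cellobiose_partition(0.16, 3.7, 0.16) # total ~18.2, catabolic ~11.6
#' @export
cellobiose_partition <- function(biomass_yield = energetics_defaults()$biomass_yield,
                                 anabolic = energetics_defaults()$anabolic_cellobiose,
                                 unaccounted_fraction = energetics_defaults()$unaccounted_fraction,
                                 cellobiose_g_per_mmol = energetics_defaults()$cellobiose_g_per_mmol) {
  stopifnot(biomass_yield > 0, anabolic >= 0,
            unaccounted_fraction >= 0, unaccounted_fraction < 1)
  total <- 1 / (biomass_yield * cellobiose_g_per_mmol)
  unaccounted <- unaccounted_fraction * total
  catabolic <- total - anabolic - unaccounted
  if (catabolic < 0) {
    stop("Partition is negative: anabolic + unaccounted exceed total cellobiose",
         call. = FALSE)
  }
  structure(
    list(total = total, anabolic = anabolic, unaccounted = unaccounted,
         catabolic = catabolic, biomass_yield = biomass_yield,
         carbon_fraction = energetics_defaults()$carbon_fraction),
    class = "cellobiose_partition"
  )
}

#' @export
print.cellobiose_partition <- function(x, ...) {
  cat("<cellobiose partition> (mmol/g cells)\n")
  cat("  total:      ", format(x$total, digits = 4),
      " (yield", x$biomass_yield, "g/g)\n")
  cat("  anabolic:   ", format(x$anabolic, digits = 4), "\n")
  cat("  unaccounted:", format(x$unaccounted, digits = 4), "\n")
  cat("  catabolic:  ", format(x$catabolic, digits = 4), "\n")
  invisible(x)
}

#' Catabolic pyrophosphate demand of glycolysis
#'
#' Each catabolic cellobiose passes PPi-dependent phosphofructokinase twice
#' (two hexose units) and yields four PEP; the fraction of PEP converted by
#' PPDK consumes one further PPi each. Combines the demand with the anabolic
#' supply into a PPi budget.
#'
#' @param partition A [cellobiose_partition()].
#' @param ppdk_fraction Fraction of the PEP-to-pyruvate flux through PPDK,
#'   in `[0, 1]` (the remainder runs through the malate shunt or pyruvate
#'   kinase, which consume no PPi).
#' @param pfk_ppi_per_cellobiose PPi consumed by PPi-PFK per cellobiose.
#' @param pep_per_cellobiose PEP produced per cellobiose.
#' @param anabolic_sources Named vector of anabolic PPi sources, mmol/g.
#' @return An object of class `ppi_budget`.
#' @examples
#' catabolic_ppi_demand(cellobiose_partition()) # ~54 mmol PPi/g cells
#' @export
catabolic_ppi_demand <- function(partition = cellobiose_partition(),
                                 ppdk_fraction = energetics_defaults()$ppdk_fraction,
                                 pfk_ppi_per_cellobiose = 2,
                                 pep_per_cellobiose = 4,
                                 anabolic_sources = energetics_defaults()$anabolic_ppi_sources) {
  stopifnot(inherits(partition, "cellobiose_partition"),
            ppdk_fraction >= 0, ppdk_fraction <= 1)
  pfk <- pfk_ppi_per_cellobiose * partition$catabolic
  ppdk <- ppdk_fraction * pep_per_cellobiose * partition$catabolic
  structure(
    list(
      anabolic_sources = anabolic_sources,
      anabolic_total = anabolic_ppi_total(anabolic_sources),
      catabolic_pfk = pfk,
      catabolic_ppdk = ppdk,
      catabolic_total = pfk + ppdk,
      ppdk_flux_fraction = ppdk_fraction,
      partition = partition
    ),
    class = "ppi_budget"
  )
}

#' @export
print.ppi_budget <- function(x, ...) {
  cat("<PPi budget> (mmol PPi/g cells)\n")
  cat("  anabolic supply:", format(x$anabolic_total, digits = 4), "\n")
  for (nm in names(x$anabolic_sources)) {
    cat("    ", format(nm, width = 14), format(x$anabolic_sources[[nm]], digits = 3), "\n")
  }
  cat("  catabolic demand:", format(x$catabolic_total, digits = 4), "\n")
  cat("     PPi-PFK:      ", format(x$catabolic_pfk, digits = 4), "\n")
  cat("     PPDK (fraction", format(x$ppdk_flux_fraction, digits = 3), "):",
      format(x$catabolic_ppdk, digits = 4), "\n")
  if (x$anabolic_total < x$catabolic_total) {
    cat("  anabolic PPi cannot satisfy catabolic demand: shortfall",
        format(x$catabolic_total - x$anabolic_total, digits = 4), "mmol/g\n")
  }
  invisible(x)
}

#' @export
tidy.ppi_budget <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(side = "anabolic", component = names(x$anabolic_sources),
                   ppi = unname(x$anabolic_sources)),
    tibble::tibble(side = "catabolic", component = c("ppi_pfk", "ppdk"),
                   ppi = c(x$catabolic_pfk, x$catabolic_ppdk))
  )
}

#' @export
glance.ppi_budget <- function(x, ...) {
  tibble::tibble(
    anabolic_total = x$anabolic_total,
    catabolic_pfk = x$catabolic_pfk,
    catabolic_ppdk = x$catabolic_ppdk,
    catabolic_total = x$catabolic_total,
    ppdk_flux_fraction = x$ppdk_flux_fraction,
    shortfall = x$catabolic_total - x$anabolic_total
  )
}

#' ATP requirement for biosynthesis after an anabolic PPi credit
#'
#' When anabolic PPi is reconsumed in reversible reactions instead of being
#' hydrolysed, each mmol replaces one mmol ATP: adjusted = base - credit, and
#' the theoretical maximum biomass yield on ATP is 1000/adjusted.
#'
#' @param base Base ATP requirement, mmol ATP per g cells.
#' @param credit Anabolic PPi reconsumed, mmol per g cells; must be below
#'   `base`.
#' @return An object of class `atp_accounting`.
#' @examples
#' atp_requirement_with_ppi_credit(34.7, 11) # 23.7 mmol/g, Y_ATPmax 42.2
#' @export
atp_requirement_with_ppi_credit <- function(base = energetics_defaults()$base_atp_requirement,
                                            credit) {
  stopifnot(base > 0, credit >= 0)
  if (credit >= base) stop("PPi credit must be smaller than the base ATP requirement",
                           call. = FALSE)
  adjusted <- base - credit
  structure(
    list(base_atp_requirement = base, ppi_credit = credit,
         adjusted_requirement = adjusted,
         y_atp_max = 1000 / adjusted,
         y_atp_base = 1000 / base),
    class = "atp_accounting"
  )
}

#' @export
print.atp_accounting <- function(x, ...) {
  cat("<ATP accounting>\n")
  cat("  base requirement:    ", format(x$base_atp_requirement, digits = 4),
      "mmol ATP/g cells (Y_ATPmax", format(x$y_atp_base, digits = 3), "g/mol)\n")
  cat("  PPi credit:          ", format(x$ppi_credit, digits = 4), "mmol/g\n")
  cat("  adjusted requirement:", format(x$adjusted_requirement, digits = 4),
      "mmol ATP/g cells (Y_ATPmax", format(x$y_atp_max, digits = 3), "g/mol)\n")
  invisible(x)
}

#' @export
glance.atp_accounting <- function(x, ...) {
  tibble::tibble(
    base_atp_requirement = x$base_atp_requirement,
    ppi_credit = x$ppi_credit,
    adjusted_requirement = x$adjusted_requirement,
    y_atp_base = x$y_atp_base,
    y_atp_max = x$y_atp_max
  )
}

#' Amino acid residues polymerised per gram of cells
#'
#' @param protein_fraction g protein per g cells.
#' @param residue_mass Mean residue mass, g/mol (free mass minus water).
#' @return mmol residues (= peptide bonds, to within one terminus) per g cells.
#' @examples
#' protein_residues_mmol() # ~4.8
#' @export
protein_residues_mmol <- function(protein_fraction = energetics_defaults()$protein_fraction,
                                  residue_mass = energetics_defaults()$residue_mass) {
  stopifnot(protein_fraction >= 0, residue_mass > 0)
  1000 * protein_fraction / residue_mass
}

#' ATP saving from PPDK-coupled protein synthesis
#'
#' With PPi reconsumed by PPDK instead of hydrolysed, one ATP is saved per
#' peptide bond; the saving relative to the total biosynthetic ATP
#' requirement, as an integer percentage.
#'
#' @inheritParams protein_residues_mmol
#' @param base Base ATP requirement, mmol/g cells.
#' @return Percent saving, rounded to the nearest integer.
#' @examples
#' protein_atp_saving() # 14
#' @export
protein_atp_saving <- function(protein_fraction = energetics_defaults()$protein_fraction,
                               residue_mass = energetics_defaults()$residue_mass,
                               base = energetics_defaults()$base_atp_requirement) {
  stopifnot(base > 0)
  residues <- protein_residues_mmol(protein_fraction, residue_mass)
  round(100 * residues / base)
}

#' Cell mass that lysis would have to release to explain extracellular amino acids
#'
#' If the observed extracellular amino acids originated from lysed cells, the
#' lysed mass is at least the amino acid mass divided by the minimum protein
#' fraction of the cells.
#'
#' @param extracellular_aa mg amino acids per liter.
#' @param min_protein_fraction Minimum g protein per g cells, in `(0, 1]`.
#' @return mg cells per liter (unrounded).
#' @examples
#' lysis_required_cell_mass(100, 0.6) # ~167
#' @export
lysis_required_cell_mass <- function(extracellular_aa,
                                     min_protein_fraction = 0.6) {
  stopifnot(extracellular_aa >= 0, min_protein_fraction > 0,
            min_protein_fraction <= 1)
  extracellular_aa / min_protein_fraction
}

#' Intracellular amino acid concentration implied by the lysis hypothesis
#'
#' If lysis of [lysis_required_cell_mass()] mg of cells released the observed
#' amino acids, the pre-lysis intracellular concentration would have been the
#' molar amount over the cytoplasmic volume of the lysed cells. The specific
#' cell volume is an explicit parameter; 2.0 ml/g reproduces the 334 ul
#' volume associated with 167 mg of cells.
#'
#' @param extracellular_aa mg amino acids per liter.
#' @param mean_aa_mass Mean free amino acid molar mass, g/mol.
#' @param min_protein_fraction Minimum protein fraction of cells.
#' @param specific_cell_volume ml per g cells.
#' @return Implied concentration, mol/liter.
#' @examples
#' lysis_implied_concentration(100, 111, 0.6, 2.0) # ~2.7 M
#' @export
lysis_implied_concentration <- function(extracellular_aa, mean_aa_mass = 111,
                                        min_protein_fraction = 0.6,
                                        specific_cell_volume = 2.0) {
  stopifnot(extracellular_aa >= 0, mean_aa_mass > 0, specific_cell_volume > 0)
  if (extracellular_aa == 0) return(0)
  aa_mmol <- extracellular_aa / mean_aa_mass
  cell_mg <- lysis_required_cell_mass(extracellular_aa, min_protein_fraction)
  volume_ml <- cell_mg / 1000 * specific_cell_volume
  aa_mmol / volume_ml
}
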