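# Atomic masses: IUPAC conventional values, fixed so results are bit-stable.
ATOMIC_MASS <- c(
  C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Cl = 35.45
)

#' Parse a molecular formula string into element counts
#'
#' Accepts Hill-style formulas such as `"C6H12O6"` or `"CHO2"` (implicit 1).
#'
#' @param formula A molecular formula string.
#' @return A named integer vector of element counts.
#' @examples
#' parse_formula("C2H3O2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("Malformed formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(n == "", 1L, as.integer(n))
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Molar mass of a formula from fixed atomic masses
#'
#' @param formula A molecular formula string.
#' @return Molar mass in g/mol.
#' @examples
#' formula_mass("C12H22O11") # cellobiose, 342.30
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(ATOMIC_MASS))
  if (length(unknown)) {
    stop("No atomic mass for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(counts * ATOMIC_MASS[names(counts)])
}

#' Elemental mass fraction of a formula
#'
#' @param formula A molecular formula string.
#' @param element Element symbol, e.g. `"C"` or `"N"`.
#' @return Dimensionless mass fraction in `[0, 1)`.
#' @export
element_fraction <- function(formula, element) {
  counts <- parse_formula(formula)
  n <- counts[element]
  if (is.na(n)) n <- 0L
  unname(n * ATOMIC_MASS[element] / formula_mass(formula))
}

# One row per compound. Organic acids carry both the free (neutral) acid and
# the anion formula; the two molar-mass conventions deliberately coexist
# because balance closure and flux computation use different ones.
registry_rows <- function() {
  r <- function(name, formula, anion_formula = NA_character_, class = "other") {
    tibble::tibble(name = name, formula = formula,
                   anion_formula = anion_formula, class = class)
  }
  dplyr::bind_rows(
    r("cellobiose", "C12H22O11", class = "sugar"),
    r("glucose", "C6H12O6", class = "sugar"),
    r("acetate", "C2H4O2", "C2H3O2", "organic_acid"),
    r("ethanol", "C2H6O", class = "alcohol"),
    r("lactate", "C3H6O3", "C3H5O3", "organic_acid"),
    r("formate", "CH2O2", "CHO2", "organic_acid"),
    r("pyruvate", "C3H4O3", "C3H3O3", "organic_acid"),
    r("isobutanol", "C4H10O", class = "alcohol"),
    r("co2", "CO2", class = "gas"),
    r("h2o", "H2O", class = "other"),
    r("urea", "CH4N2O", class = "nitrogen_source"),
    r("ammonium", "NH4", class = "nitrogen_source"),
    r("ammonium_chloride", "NH4Cl" , class = "nitrogen_source"),
    # Free (zwitterionic neutral) amino acids, not residues.
    r("alanine", "C3H7NO2", class = "amino_acid"),
    r("arginine", "C6H14N4O2", class = "amino_acid"),
    r("asparagine", "C4H8N2O3", class = "amino_acid"),
    r("aspartic_acid", "C4H7NO4", class = "amino_acid"),
    r("cysteine", "C3H7NO2S", class = "amino_acid"),
    r("glutamic_acid", "C5H9NO4", class = "amino_acid"),
    r("glutamine", "C5H10N2O3", class = "amino_acid"),
    r("glycine", "C2H5NO2", class = "amino_acid"),
    r("histidine", "C6H9N3O2", class = "amino_acid"),
    r("isoleucine", "C6H13NO2", class = "amino_acid"),
    r("leucine", "C6H13NO2", class = "amino_acid"),
    r("lysine", "C6H14N2O2", class = "amino_acid"),
    r("methionine", "C5H11NO2S", class = "amino_acid"),
    r("phenylalanine", "C9H11NO2", class = "amino_acid"),
    r("proline", "C5H9NO2", class = "amino_acid"),
    r("serine", "C3H7NO3", class = "amino_acid"),
    r("threonine", "C4H9NO3", class = "amino_acid"),
    r("tryptophan", "C11H12N2O2", class = "amino_acid"),
    r("tyrosine", "C9H11NO3", class = "amino_acid"),
    r("valine", "C5H11NO2", class = "amino_acid")
  )
}

#' Built-in compound registry
#'
#' One row per chemical species with its molecular formula, the anion formula
#' where a deprotonated form exists, molar masses under the free-acid and
#' anion conventions, and carbon/nitrogen atom counts. Covers the fermentation
#' products, substrates, nitrogen sources and the twenty standard amino acids
#' (as free molecules, not residues).
#'
#' @param extra Optional tibble of additional rows with columns `name`,
#'   `formula`, and optionally `anion_formula` and `class`.
#' @return A tibble with columns `name`, `formula`, `anion_formula`, `class`,
#'   `mass_free_acid`, `mass_anion`, `carbon_atoms`, `nitrogen_atoms`.
#' @examples
#' compound_registry()
#' @export
compound_registry <- function(extra = NULL) {
  if (is.null(extra) && !is.null(.ppiflux_env$registry)) {
    return(.ppiflux_env$registry)
  }
  rows <- registry_rows()
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (!all(c("name", "formula") %in% names(extra))) {
      stop("`extra` needs at least columns `name` and `formula`", call. = FALSE)
    }
    if (!"anion_formula" %in% names(extra)) extra$anion_formula <- NA_character_
    if (!"class" %in% names(extra)) extra$class <- "user"
    rows <- dplyr::bind_rows(rows, extra[c("name", "formula", "anion_formula", "class")])
  }
  if (anyDuplicated(rows$name)) {
    stop("Duplicate registry entries: ",
         paste(unique(rows$name[duplicated(rows$name)]), collapse = ", "),
         call. = FALSE)
  }
  rows$mass_free_acid <- unname(vapply(rows$formula, formula_mass, numeric(1)))
  rows$mass_anion <- unname(ifelse(
    is.na(rows$anion_formula), NA_real_,
    vapply(rows$anion_formula, function(f) if (is.na(f)) NA_real_ else formula_mass(f), numeric(1))
  ))
  counts <- lapply(rows$formula, parse_formula)
  rows$carbon_atoms <- vapply(counts, function(x) {
    n <- x["C"]; if (is.na(n)) 0L else as.integer(n)
  }, integer(1))
  rows$nitrogen_atoms <- vapply(counts, function(x) {
    n <- x["N"]; if (is.na(n)) 0L else as.integer(n)
  }, integer(1))
  if (is.null(extra)) .ppiflux_env$registry <- rows
  rows
}

.ppiflux_env <- new.env(parent = emptyenv())

registry_lookup <- function(species, registry = compound_registry()) {
  i <- match(species, registry$name)
  if (anyNA(i)) {
    stop("Unknown species: ", paste(species[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  registry[i, , drop = FALSE]
}

#' Molar mass of a registered species under a mass convention
#'
#' Balance closure reproduces published carbon balances only with anion masses
#' for the organic acids, while specific-flux tables reproduce published
#' values only with free-acid masses, so the convention is always an explicit
#' argument. For species without an anion form (alcohols, sugars, amino
#' acids), the anion convention falls back to the only mass the species has.
#'
#' @param species Character vector of registry names.
#' @param convention `"free_acid"` or `"anion"`.
#' @param registry A compound registry tibble.
#' @return Numeric vector of molar masses, g/mol.
#' @examples
#' molar_mass("acetate", "anion")     # 59.04
#' molar_mass("acetate", "free_acid") # 60.05
#' @export
molar_mass <- function(species, convention = c("free_acid", "anion"),
                       registry = compound_registry()) {
  convention <- match.arg(convention)
  rows <- registry_lookup(species, registry)
  if (convention == "free_acid") {
    rows$mass_free_acid
  } else {
    ifelse(is.na(rows$mass_anion), rows$mass_free_acid, rows$mass_anion)
  }
}

#' Convert a mass concentration to a molar concentration
#'
#' @param concentration Concentration in mg/liter (vectorised).
#' @param species Registry name(s), recycled against `concentration`.
#' @inheritParams molar_mass
#' @return Concentration in mmol/liter.
#' @examples
#' to_mmol(1062.4, "acetate", "anion")     # 17.995
#' to_mmol(1062.4, "acetate", "free_acid") # 17.692
#' @export
to_mmol <- function(concentration, species, convention = c("free_acid", "anion"),
                    registry = compound_registry()) {
  convention <- match.arg(convention)
  if (any(concentration < 0, na.rm = TRUE)) {
    stop("Concentrations must be >= 0", call. = FALSE)
  }
  concentration / molar_mass(species, convention, registry)
}

#' Elemental carbon or nitrogen content of a mass concentration
#'
#' @inheritParams to_mmol
#' @param element `"C"` or `"N"`.
#' @return mg of element per liter.
#' @export
element_mass <- function(concentration, species, element = c("C", "N"),
                         convention = c("free_acid", "anion"),
                         registry = compound_registry()) {
  element <- match.arg(element)
  convention <- match.arg(convention)
  rows <- registry_lookup(species, registry)
  atoms <- if (element == "C") rows$carbon_atoms else rows$nitrogen_atoms
  mass <- molar_mass(species, convention, registry)
  concentration * atoms * ATOMIC_MASS[[element]] / mass
}

#' Protein elemental composition
#'
#' Mass fractions of carbon and nitrogen in cell and supernatant protein,
#' defaulting to 0.532 g C/g and 0.161 g N/g.
#'
#' @param c_frac g carbon per g protein.
#' @param n_frac g nitrogen per g protein.
#' @return A list of class `protein_composition`.
#' @export
protein_composition <- function(c_frac = 0.532, n_frac = 0.161) {
  stopifnot(c_frac > 0, c_frac < 1, n_frac > 0, n_frac < 1)
  structure(list(c_frac = c_frac, n_frac = n_frac),
            class = "protein_composition")
}

#' Amino acid concentration profile
#'
#' Per-amino-acid concentrations in a culture supernatant, with optional
#' declared elemental totals. Declared totals are carried separately from the
#' elemental sums this package computes because published totals are not
#' always reproducible from the listed free amino acids; downstream
#' nitrogen-uptake accounting consumes the declared total when present.
#'
#' @param concentrations Named numeric vector, mg/liter per amino acid.
#' @param declared_total_c Optional declared total carbon, mg C/liter.
#' @param declared_total_n Optional declared total nitrogen, mg N/liter.
#' @return A list of class `aa_profile`.
#' @export
amino_acid_profile <- function(concentrations = numeric(),
                               declared_total_c = NULL,
                               declared_total_n = NULL) {
  if (length(concentrations)) {
    stopifnot(!is.null(names(concentrations)), all(concentrations >= 0))
  }
  structure(
    list(concentrations = concentrations,
         declared_total_c = declared_total_c,
         declared_total_n = declared_total_n),
    class = "aa_profile"
  )
}

#' Total amino acid concentration of a profile
#'
#' @param profile An [amino_acid_profile()].
#' @return Total concentration, mg/liter.
#' @export
profile_total <- function(profile) {
  stopifnot(inherits(profile, "aa_profile"))
  sum(profile$concentrations)
}

#' Elemental carbon or nitrogen in an amino acid profile
#'
#' Sums concentration times the elemental mass fraction of each free amino
#' acid. `use_declared = TRUE` returns the declared total when one was
#' recorded, falling back to the elemental sum.
#'
#' @param profile An [amino_acid_profile()].
#' @param element `"C"` or `"N"`.
#' @param use_declared Prefer the declared total when available.
#' @param registry A compound registry tibble.
#' @return mg element/liter.
#' @export
profile_element_mass <- function(profile, element = c("C", "N"),
                                 use_declared = FALSE,
                                 registry = compound_registry()) {
  stopifnot(inherits(profile, "aa_profile"))
  element <- match.arg(element)
  if (use_declared) {
    declared <- if (element == "C") profile$declared_total_c else profile$declared_total_n
    if (!is.null(declared)) return(declared)
  }
  if (!length(profile$concentrations)) return(0)
  sum(element_mass(unname(profile$concentrations),
                   names(profile$concentrations),
                   element, "free_acid", registry))
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("<amino acid profile>", length(x$concentrations), "species, total",
      format(profile_total(x), digits = 4), "mg/liter\n")
  if (!is.null(x$declared_total_c)) {
    cat("  declared total C:", x$declared_total_c, "mg C/liter\n")
  }
  if (!is.null(x$declared_total_n)) {
    cat("  declared total N:", x$declared_total_n, "mg N/liter\n")
  }
  invisible(x)
}

#' @export
tidy.aa_profile <- function(x, registry = compound_registry(), ...) {
  if (!length(x$concentrations)) {
    return(tibble::tibble(amino_acid = character(), concentration = numeric(),
                          carbon = numeric(), nitrogen = numeric()))
  }
  tibble::tibble(
    amino_acid = names(x$concentrations),
    concentration = unname(x$concentrations),
    carbon = element_mass(unname(x$concentrations), names(x$concentrations),
                          "C", "free_acid", registry),
    nitrogen = element_mass(unname(x$concentrations), names(x$concentrations),
                            "N", "free_acid", registry)
  )
}
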