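# Pyruvate-family products whose molar fluxes sum (valine doubled, since one
# valine consumes two pyruvate) to the total flux through the pyruvate node.
PYRUVATE_FAMILY <- c("acetate", "ethanol", "lactate", "pyruvate", "valine")

#' Specific molar production rate per gram of cell nitrogen
#'
#' q = (c / M) * D / (cell N / 1000). Normalisation is per g cell nitrogen
#' rather than dry weight because nitrogen tracks the catalytic (protein)
#' machinery even when the cellular C/N ratio shifts.
#'
#' @param concentration mg/liter (vectorised).
#' @param species Registry name(s).
#' @param dilution_rate D, 1/h.
#' @param cell_nitrogen mg N/liter; must be positive.
#' @param convention Mass convention; published flux tables are reproduced
#'   with `"free_acid"`.
#' @param registry A compound registry tibble.
#' @return mmol per g cell N per hour.
#' @examples
#' specific_flux(1062.4, "acetate", 0.1, 102.0) # 17.34
#' @export
specific_flux <- function(concentration, species, dilution_rate, cell_nitrogen,
                          convention = c("free_acid", "anion"),
                          registry = compound_registry()) {
  convention <- match.arg(convention)
  if (any(cell_nitrogen <= 0)) stop("cell_nitrogen must be positive", call. = FALSE)
  to_mmol(concentration, species, convention, registry) * dilution_rate /
    (cell_nitrogen / 1000)
}

#' Specific mass rate per gram of cell nitrogen
#'
#' Used for pooled quantities without a single molar mass (excreted amino
#' acids, supernatant protein).
#'
#' @inheritParams specific_flux
#' @return mg per g cell N per hour.
#' @examples
#' mass_flux(90.8, 0.1, 102.0) # 89.0
#' @export
mass_flux <- function(concentration, dilution_rate, cell_nitrogen) {
  if (any(cell_nitrogen <= 0)) stop("cell_nitrogen must be positive", call. = FALSE)
  concentration * dilution_rate / (cell_nitrogen / 1000)
}

#' Specific flux table for a chemostat condition
#'
#' Computes the specific molar flux of every registered product, the molar
#' valine flux from the amino acid profile, the mass fluxes of excreted amino
#' acids and supernatant protein, and the derived aggregates: total pyruvate
#' flux and nitrogen uptake flux.
#'
#' @param condition A [chemostat_condition()].
#' @param convention Mass convention (default `"free_acid"`).
#' @param protein A [protein_composition()] for the nitrogen uptake flux.
#' @param normalization Biomass basis: `"cell_nitrogen"` (default; nitrogen
#'   tracks the catalytic machinery when cellular C/N shifts) or
#'   `"dry_weight"`, which estimates dry mass as cell carbon over
#'   `carbon_fraction`.
#' @param carbon_fraction g C per g dry cells, used only for the dry-weight
#'   basis.
#' @param registry A compound registry tibble.
#' @return An object of class `flux_table`: a tibble of per-species rates
#'   with aggregate attributes; see [tidy.flux_table()], [glance.flux_table()].
#' @export
flux_table <- function(condition, convention = c("free_acid", "anion"),
                       protein = protein_composition(),
                       normalization = c("cell_nitrogen", "dry_weight"),
                       carbon_fraction = 0.45,
                       registry = compound_registry()) {
  stopifnot(inherits(condition, "chemostat_condition"))
  convention <- match.arg(convention)
  normalization <- match.arg(normalization)
  D <- condition$dilution_rate
  cn <- condition$cell_nitrogen
  if (is.na(cn) || cn <= 0) stop("cell_nitrogen must be positive", call. = FALSE)
  if (normalization == "dry_weight") {
    if (is.na(condition$cell_carbon) || condition$cell_carbon <= 0) {
      stop("cell_carbon must be positive for dry-weight normalization",
           call. = FALSE)
    }
    cn <- condition$cell_carbon / carbon_fraction
  }

  basis <- if (normalization == "dry_weight") "DW" else "N"
  unit_molar <- paste0("mmol/g ", basis, "/h")
  unit_mass <- paste0("mg/g ", basis, "/h")

  species <- names(condition$products)
  q <- if (length(species)) {
    specific_flux(unname(condition$products[species]), species, D, cn,
                  convention, registry)
  } else numeric()
  rows <- tibble::tibble(species = species %||% character(), q = q,
                         unit = unit_molar)

  val <- condition$amino_acids$concentrations["valine"]
  if (!is.na(val)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      species = "valine",
      q = specific_flux(unname(val), "valine", D, cn, convention, registry),
      unit = unit_molar
    ))
  }

  aa_total <- profile_total(condition$amino_acids)
  rows <- dplyr::bind_rows(
    rows,
    tibble::tibble(species = "excreted_amino_acids",
                   q = mass_flux(aa_total, D, cn), unit = unit_mass),
    tibble::tibble(species = "supernatant_protein",
                   q = mass_flux(condition$supernatant_protein, D, cn),
                   unit = unit_mass)
  )

  out <- structure(rows, class = c("flux_table", class(rows)))
  attr(out, "dilution_rate") <- D
  attr(out, "cell_nitrogen") <- cn
  attr(out, "convention") <- convention
  attr(out, "normalization") <- normalization
  attr(out, "q_total_pyruvate") <- total_pyruvate_flux(out)
  # nitrogen uptake is defined per g cell N; not rebased onto dry weight
  attr(out, "q_nitrogen_uptake") <- if (normalization == "cell_nitrogen") {
    tryCatch(nitrogen_uptake_flux(condition, protein, registry),
             error = function(e) NA_real_)
  } else NA_real_
  out
}

flux_of <- function(table, species) {
  i <- which(table$species == species & startsWith(table$unit, "mmol"))
  if (!length(i)) return(NA_real_)
  table$q[i[1]]
}

#' Total flux through the pyruvate branch point
#'
#' Sum of the molar fluxes of acetate, ethanol, lactate, and excreted
#' pyruvate, plus twice the valine flux. Missing species count as zero flux
#' only if absent from the table entirely alongside at least one present
#' member; an all-absent table errors.
#'
#' @param table A `flux_table`.
#' @return mmol/g cell N/h.
#' @export
total_pyruvate_flux <- function(table) {
  q <- vapply(PYRUVATE_FAMILY, flux_of, numeric(1), table = table)
  if (all(is.na(q))) {
    stop("No pyruvate-family fluxes in table", call. = FALSE)
  }
  q[is.na(q)] <- 0
  unname(q["acetate"] + q["ethanol"] + q["lactate"] + q["pyruvate"] +
           2 * q["valine"])
}

#' Specific nitrogen uptake flux
#'
#' Sums nitrogen in cells, excreted amino acids (declared total when
#' recorded) and supernatant protein, converts to mmol N and normalises per
#' gram cell nitrogen: ((cell N + aa N + protein N) / 14.007) * D /
#' (cell N / 1000).
#'
#' @inheritParams flux_table
#' @return mmol N per g cell N per hour.
#' @export
nitrogen_uptake_flux <- function(condition, protein = protein_composition(),
                                 registry = compound_registry()) {
  stopifnot(inherits(condition, "chemostat_condition"))
  cn <- condition$cell_nitrogen
  if (is.na(cn) || cn <= 0) stop("cell_nitrogen must be positive", call. = FALSE)
  aa_n <- profile_element_mass(condition$amino_acids, "N",
                               use_declared = TRUE, registry = registry)
  n_total <- cn + aa_n + condition$supernatant_protein * protein$n_frac
  (n_total / ATOMIC_MASS[["N"]]) * condition$dilution_rate / (cn / 1000)
}

#' Fold change between two fluxes
#'
#' @param q_a Numerator flux.
#' @param q_b Denominator (reference) flux; must be nonzero.
#' @return q_a / q_b.
#' @examples
#' fold_change(2.64, 0.13) # ~20-fold
#' @export
fold_change <- function(q_a, q_b) {
  if (any(q_b == 0)) stop("Reference flux is zero", call. = FALSE)
  q_a / q_b
}

#' A product's share of the total pyruvate flux
#'
#' @param table A `flux_table`.
#' @param species One of the pyruvate-family products.
#' @return Percent of the total pyruvate flux.
#' @export
product_fraction <- function(table, species) {
  if (!species %in% PYRUVATE_FAMILY) {
    stop(species, " is not a pyruvate-family product", call. = FALSE)
  }
  total <- attr(table, "q_total_pyruvate")
  if (is.null(total)) total <- total_pyruvate_flux(table)
  if (total <= 0) stop("Total pyruvate flux is not positive", call. = FALSE)
  q <- flux_of(table, species)
  if (is.na(q)) q <- 0
  100 * q / total
}

#' @export
print.flux_table <- function(x, ...) {
  cat("<flux table>  D =", attr(x, "dilution_rate"), "1/h, cell N =",
      attr(x, "cell_nitrogen"), "mg/L,", attr(x, "convention"), "masses\n")
  print(tibble::as_tibble(x), n = nrow(x))
  cat("q_total_pyruvate:", format(attr(x, "q_total_pyruvate"), digits = 4),
      "mmol/g N/h\n")
  qn <- attr(x, "q_nitrogen_uptake")
  if (!is.na(qn)) {
    cat("q_nitrogen_uptake:", format(qn, digits = 4), "mmol/g N/h\n")
  }
  invisible(x)
}

#' @export
tidy.flux_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.flux_table <- function(x, ...) {
  tibble::tibble(
    dilution_rate = attr(x, "dilution_rate"),
    cell_nitrogen = attr(x, "cell_nitrogen"),
    convention = attr(x, "convention"),
    q_total_pyruvate = attr(x, "q_total_pyruvate"),
    q_nitrogen_uptake = attr(x, "q_nitrogen_uptake")
  )
}
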