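#' A steady-state chemostat condition
#'
#' Bundles one steady state: dilution rate, feed and residual substrate,
#' product concentrations, cell elemental carbon and nitrogen, supernatant
#' protein, and the amino acid profile. All concentrations are mg/liter.
#' Species absent from `residual` or `products` are treated as not detected
#' (exactly zero); species named in `not_detected` are recorded as measured
#' below the detection limit and also treated as zero.
#'
#' @param organism Label for the organism / strain.
#' @param dilution_rate Dilution rate D in 1/h; must be positive.
#' @param feed Named numeric vector of feed concentrations, mg/liter.
#' @param products Named numeric vector of product concentrations, mg/liter.
#' @param residual Named numeric vector of residual substrate, mg/liter.
#' @param cell_carbon Cell (pellet) carbon, mg C/liter.
#' @param cell_nitrogen Cell (pellet) nitrogen, mg N/liter.
#' @param supernatant_protein Extracellular protein, mg/liter.
#' @param amino_acids An [amino_acid_profile()].
#' @param feed_nitrogen Total feed nitrogen, mg N/liter (optional; needed for
#'   nitrogen recovery).
#' @param not_detected Character vector of species reported as not detected.
#' @return A list of class `chemostat_condition`.
#' @examples
#' cond <- chemostat_condition(
#'   organism = "demo", dilution_rate = 0.1,
#'   feed = c(cellobiose = 5000),
#'   products = c(acetate = 1000, ethanol = 700),
#'   cell_carbon = 300, cell_nitrogen = 100
#' )
#' cond
#' @export
chemostat_condition <- function(organism = "unknown",
                                dilution_rate,
                                feed = numeric(),
                                products = numeric(),
                                residual = numeric(),
                                cell_carbon = NA_real_,
                                cell_nitrogen = NA_real_,
                                supernatant_protein = 0,
                                amino_acids = amino_acid_profile(),
                                feed_nitrogen = NA_real_,
                                not_detected = character()) {
  stopifnot(is.numeric(dilution_rate), length(dilution_rate) == 1L,
            dilution_rate > 0)
  check_conc <- function(x, what) {
    if (length(x)) {
      if (is.null(names(x)) || any(!nzchar(names(x)))) {
        stop(what, " must be a named numeric vector", call. = FALSE)
      }
      if (any(x < 0)) stop(what, " concentrations must be >= 0", call. = FALSE)
    }
    x
  }
  structure(
    list(
      organism = organism,
      dilution_rate = dilution_rate,
      feed = check_conc(feed, "feed"),
      products = check_conc(products, "products"),
      residual = check_conc(residual, "residual"),
      cell_carbon = cell_carbon,
      cell_nitrogen = cell_nitrogen,
      supernatant_protein = supernatant_protein,
      amino_acids = amino_acids,
      feed_nitrogen = feed_nitrogen,
      not_detected = not_detected
    ),
    class = "chemostat_condition"
  )
}

product_conc <- function(condition, species) {
  x <- condition$products[species]
  x[is.na(x)] <- 0
  unname(x)
}

residual_conc <- function(condition, species) {
  x <- condition$residual[species]
  x[is.na(x)] <- 0
  unname(x)
}

#' @export
print.chemostat_condition <- function(x, ...) {
  cat("<chemostat condition>", x$organism, "\n")
  cat("  D =", x$dilution_rate, "1/h\n")
  if (length(x$feed)) {
    cat("  feed:", paste0(names(x$feed), " = ", x$feed, " mg/L", collapse = ", "), "\n")
  }
  cat("  cell C/N:", x$cell_carbon, "/", x$cell_nitrogen, "mg/L\n")
  if (length(x$products)) {
    cat("  products:", length(x$products), "species,",
        format(sum(x$products), digits = 5), "mg/L total\n")
  }
  if (length(x$amino_acids$concentrations)) {
    cat("  amino acids:", format(profile_total(x$amino_acids), digits = 4), "mg/L\n")
  }
  if (x$supernatant_protein > 0) {
    cat("  supernatant protein:", x$supernatant_protein, "mg/L\n")
  }
  invisible(x)
}

#' Tabular view of a chemostat condition
#'
#' @param x A [chemostat_condition()].
#' @param ... Unused.
#' @return A tibble with columns `species`, `concentration`, `role`.
#' @export
tidy.chemostat_condition <- function(x, ...) {
  rows <- list(
    tibble::tibble(species = names(x$feed) %||% character(),
                   concentration = unname(x$feed), role = "feed"),
    tibble::tibble(species = names(x$residual) %||% character(),
                   concentration = unname(x$residual), role = "residual"),
    tibble::tibble(species = names(x$products) %||% character(),
                   concentration = unname(x$products), role = "product"),
    tibble::tibble(species = names(x$amino_acids$concentrations) %||% character(),
                   concentration = unname(x$amino_acids$concentrations),
                   role = "amino_acid"),
    tibble::tibble(species = "cell_carbon", concentration = x$cell_carbon,
                   role = "cell_c"),
    tibble::tibble(species = "cell_nitrogen", concentration = x$cell_nitrogen,
                   role = "cell_n"),
    tibble::tibble(species = "protein", concentration = x$supernatant_protein,
                   role = "protein")
  )
  dplyr::bind_rows(rows)
}

#' Cellular carbon-to-nitrogen ratio
#'
#' @param condition A [chemostat_condition()].
#' @return g C per g N.
#' @examples
#' cn_ratio(chemostat_condition(dilution_rate = 0.1,
#'                              cell_carbon = 337.3, cell_nitrogen = 102.0))
#' @export
cn_ratio <- function(condition) {
  stopifnot(inherits(condition, "chemostat_condition"))
  if (is.na(condition$cell_nitrogen) || condition$cell_nitrogen <= 0) {
    stop("cell_nitrogen must be positive", call. = FALSE)
  }
  condition$cell_carbon / condition$cell_nitrogen
}
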