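# Steady-state chemostat emulator: at steady state, product concentration
# c = q * X_N / D for specific flux q (per g cell N) and cell nitrogen X_N.
# The generator inverts the flux computation, injects a configurable
# missing-carbon fraction into the feed, and perturbs measured
# concentrations with multiplicative lognormal noise.

#' Specification for the synthetic chemostat generator
#'
#' Defaults emulate a cellobiose-limited C. thermocellum steady state at
#' D = 0.1 1/h with 102 mg cell N/liter, a cellular C/N ratio of 3.31 g/g,
#' 16% missing carbon, and 2% multiplicative measurement noise; the default
#' ground-truth fluxes are the measured specific rates of that condition
#' (valine is carried as a molar flux and lands in the amino acid profile).
#'
#' @param ground_truth_fluxes Named vector of true specific fluxes,
#'   mmol/g cell N/h.
#' @param cell_nitrogen mg N/liter.
#' @param cell_cn_ratio g C per g N in cells.
#' @param dilution_rate D, 1/h.
#' @param missing_carbon_fraction Fraction of feed carbon not recovered in
#'   measured pools, in `[0, 1)`.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise; 0 disables noise.
#' @param seed Integer seed; one stream is derived per replicate so subsets
#'   are reproducible.
#' @param n_replicates Number of replicate conditions to generate.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(ground_truth_fluxes = c(
                             acetate = 17.34, ethanol = 14.89, formate = 5.15,
                             lactate = 0.38, pyruvate = 0.17,
                             isobutanol = 0.33, glucose = 0.11, valine = 0.13
                           ),
                           cell_nitrogen = 102.0,
                           cell_cn_ratio = 3.31,
                           dilution_rate = 0.1,
                           missing_carbon_fraction = 0.16,
                           noise_cv = 0.02,
                           seed = 1L,
                           n_replicates = 1L) {
  stopifnot(all(ground_truth_fluxes >= 0), !is.null(names(ground_truth_fluxes)),
            cell_nitrogen > 0, cell_cn_ratio > 0, dilution_rate > 0,
            missing_carbon_fraction >= 0, missing_carbon_fraction < 1,
            noise_cv >= 0, n_replicates >= 1)
  structure(
    list(ground_truth_fluxes = ground_truth_fluxes,
         cell_nitrogen = cell_nitrogen,
         cell_cn_ratio = cell_cn_ratio,
         dilution_rate = dilution_rate,
         missing_carbon_fraction = missing_carbon_fraction,
         noise_cv = noise_cv,
         seed = as.integer(seed),
         n_replicates = as.integer(n_replicates)),
    class = "generator_spec"
  )
}

replicate_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  # meanlog chosen so the multiplicative factor has expectation 1
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic chemostat conditions with known ground truth
#'
#' Noiseless product concentrations follow the steady-state relation
#' c = q * (cell N/1000) / D * M (free-acid masses); valine is placed in the
#' amino acid profile. The feed cellobiose is set so that the noiseless
#' carbon recovery (anion convention, inferred CO2) equals
#' 100 * (1 - missing_carbon_fraction). Measured concentrations are then
#' perturbed with multiplicative lognormal noise of the requested CV.
#' Deterministic given the seed.
#'
#' @param spec A [generator_spec()].
#' @param registry A compound registry tibble.
#' @return A list with `conditions` (list of [chemostat_condition()]),
#'   `truth` (the spec, plus the noiseless feed), and `spec`.
#' @export
generate_conditions <- function(spec = generator_spec(),
                                registry = compound_registry()) {
  stopifnot(inherits(spec, "generator_spec"))
  q <- spec$ground_truth_fluxes
  D <- spec$dilution_rate
  xn <- spec$cell_nitrogen

  conc0 <- q * (xn / 1000) / D *
    molar_mass(names(q), "free_acid", registry)
  aa_species <- intersect(names(conc0),
                          registry$name[registry$class == "amino_acid"])
  prod_species <- setdiff(names(conc0), aa_species)

  make_condition <- function(conc, feed_cellobiose) {
    chemostat_condition(
      organism = "synthetic",
      dilution_rate = D,
      feed = c(cellobiose = feed_cellobiose),
      products = conc[prod_species],
      residual = c(cellobiose = 0),
      cell_carbon = spec$cell_cn_ratio * xn,
      cell_nitrogen = xn,
      supernatant_protein = 0,
      amino_acids = amino_acid_profile(conc[aa_species]),
      not_detected = "cellobiose"
    )
  }

  # solve the noiseless closed balance for the feed: recovery = 100 (1 - f)
  probe <- make_condition(conc0, feed_cellobiose = 1)
  co2 <- infer_co2(probe, FALSE, "anion", registry)
  rep_probe <- carbon_recovery(probe, co2, convention = "anion",
                               registry = registry)
  carbon_out <- sum(rep_probe$components$carbon)
  carbon_in <- carbon_out / (1 - spec$missing_carbon_fraction)
  feed <- carbon_in / (element_mass(1, "cellobiose", "C", "anion", registry))
  if (feed <= 0) stop("Infeasible spec: nonpositive feed", call. = FALSE)

  conditions <- lapply(seq_len(spec$n_replicates), function(i) {
    set.seed(replicate_seed(spec$seed, i))
    noisy <- conc0 * lognormal_noise(length(conc0), spec$noise_cv)
    make_condition(noisy, feed)
  })

  list(conditions = conditions,
       truth = list(fluxes = q, feed_cellobiose = feed,
                    missing_carbon_fraction = spec$missing_carbon_fraction),
       spec = spec)
}

#' Re-estimate fluxes from generated conditions and score the recovery
#'
#' Applies the specific-flux computation (free-acid masses) to each replicate
#' and summarises estimates against the generator's ground truth.
#'
#' @param generated Result of [generate_conditions()].
#' @param registry A compound registry tibble.
#' @return A tibble with one row per species: ground `truth`, `estimate`
#'   (mean over replicates), `sd`, and `relative_error` of the mean.
#' @export
recover_fluxes <- function(generated, registry = compound_registry()) {
  stopifnot(length(generated$conditions) >= 1L)
  truth <- generated$truth$fluxes
  est <- vapply(generated$conditions, function(cond) {
    tab <- flux_table(cond, "free_acid", registry = registry)
    vapply(names(truth), flux_of, numeric(1), table = tab)
  }, numeric(length(truth)))
  est <- matrix(est, nrow = length(truth),
                dimnames = list(names(truth), NULL))
  m <- rowMeans(est)
  s <- apply(est, 1, stats::sd)
  tibble::tibble(
    species = names(truth),
    truth = unname(truth),
    estimate = unname(m),
    sd = unname(s),
    relative_error = ifelse(truth > 0, abs(m - truth) / truth,
                            abs(m - truth))
  )
}
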