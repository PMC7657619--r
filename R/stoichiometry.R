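# Exact rational arithmetic on integer numerator/denominator pairs. All
# stoichiometric coefficients stay rational so pathway summation cancels
# intermediates bit-exactly; floating point never enters.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

rat_norm <- function(num, den) {
  stopifnot(all(den != 0))
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn
  den <- den * sgn
  g <- mapply(rat_gcd, num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

rat_add <- function(n1, d1, n2, d2) rat_norm(n1 * d2 + n2 * d1, d1 * d2)
rat_mul <- function(n1, d1, n2, d2) rat_norm(n1 * n2, d1 * d2)

parse_rational <- function(text) {
  text <- trimws(text)
  if (grepl("^-?[0-9]+$", text)) {
    return(list(num = as.numeric(text), den = 1))
  }
  if (grepl("^-?[0-9]+/[0-9]+$", text)) {
    parts <- strsplit(text, "/", fixed = TRUE)[[1]]
    return(rat_norm(as.numeric(parts[1]), as.numeric(parts[2])))
  }
  stop("Not an integer or rational coefficient: '", text, "'", call. = FALSE)
}

format_rational <- function(num, den) {
  ifelse(den == 1, as.character(num), paste0(num, "/", den))
}

# Canonical species spellings; subscripted variants map onto one name.
SPECIES_ALIASES <- c(
  "PP_i" = "PPi", "PP_i_" = "PPi", "P_i" = "Pi", "P_i_" = "Pi",
  "CO_2" = "CO2", "CO_2_" = "CO2", "H_2O" = "H2O",
  "ferredoxin_red" = "ferredoxinred", "ferredoxin_ox" = "ferredoxinox"
)

canonical_species <- function(x) {
  hit <- unname(SPECIES_ALIASES[x])
  ifelse(is.na(hit), x, hit)
}

# Phosphate pseudo-element ledger for abstract species without molecular
# formulas, so phosphate conservation is checkable on symbolic equations.
PSEUDO_P <- c(
  ATP = 3, ADP = 2, AMP = 1, GTP = 3, GDP = 2, PPi = 2, Pi = 1, PEP = 1,
  F6P = 1, FBP = 2, C3P = 1, C4P = 1, C5P = 1, C6P = 1, C7P = 1, SBP = 2,
  G6P = 1, G1P = 1, NAD = 2, NADH = 2, NADP = 3, NADPH = 3
)

#' Construct a reaction with exact rational stoichiometry
#'
#' @param species Character vector of species names (canonicalised through
#'   the alias table, e.g. `"PP_i"` becomes `"PPi"`).
#' @param num,den Integer numerators and denominators of the coefficients;
#'   negative numerators mark consumed species.
#' @param name Reaction label.
#' @param reversible Logical flag recorded from `<->` arrows.
#' @return An object of class `reaction`.
#' @export
reaction <- function(species, num, den = rep(1, length(species)),
                     name = "", reversible = FALSE) {
  stopifnot(length(species) == length(num), length(num) == length(den))
  species <- canonical_species(species)
  # merge duplicates with exact addition
  if (anyDuplicated(species)) {
    agg_n <- numeric(0); agg_d <- numeric(0); agg_s <- character(0)
    for (i in seq_along(species)) {
      j <- match(species[i], agg_s)
      if (is.na(j)) {
        agg_s <- c(agg_s, species[i]); agg_n <- c(agg_n, num[i]); agg_d <- c(agg_d, den[i])
      } else {
        r <- rat_add(agg_n[j], agg_d[j], num[i], den[i])
        agg_n[j] <- r$num; agg_d[j] <- r$den
      }
    }
    species <- agg_s; num <- agg_n; den <- agg_d
  }
  r <- rat_norm(num, den)
  keep <- r$num != 0
  species <- species[keep]; num <- r$num[keep]; den <- r$den[keep]
  if (!any(num < 0) || !any(num > 0)) {
    stop("A reaction needs at least one consumed and one produced species",
         call. = FALSE)
  }
  structure(
    list(name = name, species = species, num = num, den = den,
         reversible = reversible),
    class = "reaction"
  )
}

#' Parse a plain-text reaction equation
#'
#' Accepts equations of the form `"a A + b B -> c C"`, with integer or
#' rational (`"1/2"`) coefficients, an omitted coefficient meaning 1, and
#' `"<->"` marking a reversible reaction. Species appearing on both sides are
#' merged to their net coefficient; an empty net is an error.
#'
#' @param text Equation string.
#' @param name Optional reaction label.
#' @return A [reaction()].
#' @examples
#' parse_reaction("PEP + AMP + PPi -> pyruvate + ATP + Pi", name = "PPDK")
#' @export
parse_reaction <- function(text, name = "") {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("→", "->", text)
  reversible <- grepl("<->", text, fixed = TRUE)
  arrow <- if (reversible) "<->" else "->"
  sides <- strsplit(text, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("Malformed reaction (need exactly one arrow): ", text, call. = FALSE)
  }
  parse_side <- function(side, sign) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (!length(terms)) stop("Empty reaction side in: ", text, call. = FALSE)
    out <- lapply(terms, function(term) {
      m <- regmatches(term, regexec("^([0-9]+(?:/[0-9]+)?)?\\s*(\\S.*)$", term))[[1]]
      if (length(m) < 3L || !nzchar(m[3])) {
        stop("Malformed term '", term, "' in: ", text, call. = FALSE)
      }
      coef <- if (nzchar(m[2])) parse_rational(m[2]) else list(num = 1, den = 1)
      list(species = trimws(m[3]), num = sign * coef$num, den = coef$den)
    })
    out
  }
  terms <- c(parse_side(sides[1], -1), parse_side(sides[2], 1))
  reaction(
    species = vapply(terms, `[[`, character(1), "species"),
    num = vapply(terms, `[[`, numeric(1), "num"),
    den = vapply(terms, `[[`, numeric(1), "den"),
    name = name, reversible = reversible
  )
}

#' Format a reaction as an equation string
#'
#' @param x A [reaction()].
#' @param ... Unused.
#' @return The equation as a single string.
#' @export
format.reaction <- function(x, ...) {
  fmt_side <- function(sel) {
    coefs <- format_rational(abs(x$num[sel]), x$den[sel])
    paste(ifelse(coefs == "1", x$species[sel],
                 paste(coefs, x$species[sel])), collapse = " + ")
  }
  arrow <- if (isTRUE(x$reversible)) "<->" else "->"
  paste(fmt_side(x$num < 0), arrow, fmt_side(x$num > 0))
}

#' @export
print.reaction <- function(x, ...) {
  if (nzchar(x$name)) cat(x$name, ": ", sep = "")
  cat(format(x), "\n")
  invisible(x)
}

#' @export
tidy.reaction <- function(x, ...) {
  tibble::tibble(
    species = x$species,
    coefficient = x$num / x$den,
    numerator = x$num,
    denominator = x$den,
    role = ifelse(x$num < 0, "consumed", "produced")
  )
}

#' A weighted combination of reactions
#'
#' @param reactions A list of [reaction()] objects (or a single reaction).
#' @param multipliers Rational multipliers, one per reaction, given as
#'   integers or strings like `"1/3"`; nonzero.
#' @param name Label for the combination.
#' @return An object of class `pathway_combination`.
#' @export
pathway_combination <- function(reactions, multipliers = NULL, name = "") {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  stopifnot(length(reactions) >= 1L,
            all(vapply(reactions, inherits, logical(1), "reaction")))
  if (is.null(multipliers)) multipliers <- rep(1, length(reactions))
  stopifnot(length(multipliers) == length(reactions))
  mult <- lapply(multipliers, function(m) {
    if (is.character(m)) parse_rational(m) else rat_norm(m, 1)
  })
  if (any(vapply(mult, function(m) m$num == 0, logical(1)))) {
    stop("Multipliers must be nonzero", call. = FALSE)
  }
  structure(list(reactions = reactions, multipliers = mult, name = name),
            class = "pathway_combination")
}

#' Sum a pathway combination into its net reaction
#'
#' Coefficient-weighted sum with exact rational cancellation; species with
#' net coefficient zero (pathway intermediates) vanish from the result.
#'
#' @param combo A [pathway_combination()], or a list of reactions.
#' @param multipliers Passed to [pathway_combination()] when `combo` is a
#'   plain list.
#' @param name Name for the net reaction.
#' @return A [reaction()].
#' @examples
#' ppdk <- parse_reaction("PEP + AMP + PPi -> pyruvate + ATP + Pi")
#' ak <- parse_reaction("2 ADP -> AMP + ATP")
#' combine(list(ppdk, ak)) # PEP + 2 ADP + PPi -> pyruvate + 2 ATP + Pi
#' @export
combine <- function(combo, multipliers = NULL, name = "") {
  if (!inherits(combo, "pathway_combination")) {
    combo <- pathway_combination(combo, multipliers)
  }
  acc_s <- character(0); acc_n <- numeric(0); acc_d <- numeric(0)
  for (i in seq_along(combo$reactions)) {
    rx <- combo$reactions[[i]]
    m <- combo$multipliers[[i]]
    for (j in seq_along(rx$species)) {
      term <- rat_mul(rx$num[j], rx$den[j], m$num, m$den)
      k <- match(rx$species[j], acc_s)
      if (is.na(k)) {
        acc_s <- c(acc_s, rx$species[j])
        acc_n <- c(acc_n, term$num); acc_d <- c(acc_d, term$den)
      } else {
        r <- rat_add(acc_n[k], acc_d[k], term$num, term$den)
        acc_n[k] <- r$num; acc_d[k] <- r$den
      }
    }
  }
  keep <- acc_n != 0
  if (nzchar(combo$name) && !nzchar(name)) name <- combo$name
  reaction(acc_s[keep], acc_n[keep], acc_d[keep], name = name)
}

#' Check elemental (and phosphate pseudo-element) balance of a reaction
#'
#' For species with molecular formulas in the registry, nets every element;
#' abstract species (ATP, PEP, sugar phosphates, ...) contribute to a
#' phosphate pseudo-element `P` through a built-in ledger, so conservation of
#' phosphate groups is verifiable on symbolic equations. Species with neither
#' a formula nor a ledger entry are skipped with a warning (suppressable via
#' `quiet`).
#'
#' @param x A [reaction()].
#' @param registry A compound registry tibble.
#' @param quiet Suppress the skipped-species warning.
#' @return Named numeric vector of net element counts (all zero = balanced
#'   over the accountable species).
#' @export
element_balance <- function(x, registry = compound_registry(), quiet = FALSE) {
  stopifnot(inherits(x, "reaction"))
  net <- numeric(0)
  skipped <- character(0)
  coef <- x$num / x$den
  for (i in seq_along(x$species)) {
    sp <- x$species[i]
    # symbolic equations write CO2/H2O in upper case; registry names are lower
    row <- registry[registry$name %in% c(sp, tolower(sp)), , drop = FALSE]
    if (nrow(row) == 1L) {
      counts <- parse_formula(row$formula)
      for (el in names(counts)) {
        net[el] <- (if (is.na(net[el])) 0 else net[el]) + coef[i] * counts[[el]]
      }
    } else if (sp %in% names(PSEUDO_P)) {
      net["P"] <- (if (is.na(net["P"])) 0 else net["P"]) + coef[i] * PSEUDO_P[[sp]]
    } else {
      skipped <- c(skipped, sp)
    }
  }
  if (length(skipped) && !quiet) {
    warning("Species without formula or phosphate ledger skipped: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  }
  if (!length(net)) return(stats::setNames(numeric(0), character(0)))
  # exact rational sums of integers: round away representation fuzz
  zapsmall(net)
}

#' Net ATP yield per glucose of pyrophosphate-dependent glycolysis
#'
#' The pyrophosphate-dependent pathway nets 5 ATP gross and consumes 3 PPi
#' per glucose; if generating each PPi from ATP costs `ppi_atp_cost` ATP the
#' net yield is gross - 3 * cost. The gross ATP and PPi counts are read from
#' the canned `pp_glycolysis_net` reaction, not hard-coded.
#'
#' @param ppi_atp_cost ATP spent per PPi supplied (e.g. 0.5 when a
#'   proton-pumping pyrophosphatase makes two PPi per ATP equivalent; 1 for
#'   direct ATP + Pi -> ADP + PPi).
#' @return Net ATP per glucose.
#' @examples
#' net_atp_per_glucose(0.5) # 3.5
#' net_atp_per_glucose(1)   # 2, the classical yield
#' @export
net_atp_per_glucose <- function(ppi_atp_cost) {
  stopifnot(ppi_atp_cost >= 0)
  gly <- canned_pathways()$pp_glycolysis_net
  coef <- gly$num / gly$den
  per_glucose <- -coef[match("glucose", gly$species)]
  gross_atp <- coef[match("ATP", gly$species)]
  ppi_used <- -coef[match("PPi", gly$species)]
  (gross_atp - ppi_used * ppi_atp_cost) / per_glucose
}

#' ATP-equivalent cost of a net reaction
#'
#' Counts consumed minus produced high-energy phosphoryl donors, by default
#' weighting ATP, GTP and PEP at one ATP equivalent each (PEP because its
#' conversion to pyruvate would otherwise yield one ATP).
#'
#' @param x A [reaction()].
#' @param weights Named vector of ATP-equivalents per species.
#' @return Net ATP equivalents consumed by the reaction.
#' @export
atp_equivalents <- function(x, weights = c(ATP = 1, GTP = 1, PEP = 1)) {
  stopifnot(inherits(x, "reaction"))
  coef <- x$num / x$den
  w <- weights[x$species]
  w[is.na(w)] <- 0
  -sum(coef * w)
}
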