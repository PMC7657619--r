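CONDITION_ROLES <- c("feed", "residual", "product", "cell_c", "cell_n",
                     "protein", "amino_acid")

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' ppiflux_example()
#' @export
ppiflux_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ppiflux")))
  }
  path <- system.file("extdata", file, package = "ppiflux")
  if (!nzchar(path)) stop("No packaged file called ", file, call. = FALSE)
  path
}

detect_delim <- function(lines) {
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return("\t")
  if (sum(grepl("\t", body)) >= sum(grepl(",", body))) "\t" else ","
}

parse_metadata <- function(lines) {
  meta_lines <- grep("^#\\s*[A-Za-z_]+\\s*:", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    out[[key]] <- val
  }
  out
}

meta_num <- function(meta, key) {
  if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
}

#' Read a chemostat condition from a delimited text file
#'
#' The file carries a metadata block of `# key: value` comment lines
#' (`organism` and `dilution_rate` are required; `feed_nitrogen`,
#' `aa_total_carbon`, `aa_total_nitrogen` optional) followed by a delimited
#' table (tab or comma, auto-detected) with columns `species`,
#' `concentration_mg_per_l`, `role`. Roles come from the fixed vocabulary
#' feed / residual / product / cell_c / cell_n / protein / amino_acid.
#' A concentration of `ND` (not detected) is read as exactly zero and the
#' species recorded in the condition's `not_detected` flag. Duplicate rows of
#' the same species and role are summed. Unknown species are rejected unless
#' the registry has been extended to cover them.
#'
#' @param path File path.
#' @param registry A compound registry tibble.
#' @return A [chemostat_condition()].
#' @examples
#' read_condition(ppiflux_example("chemostat_cthermocellum.tsv"))
#' @export
read_condition <- function(path, registry = compound_registry()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  meta <- parse_metadata(lines)
  if (is.null(meta$dilution_rate)) {
    stop("Condition file ", path, " lacks required metadata `dilution_rate`",
         call. = FALSE)
  }
  delim <- detect_delim(lines)
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, delim, fixed = TRUE)
  header <- trimws(fields[[1]])
  required <- c("species", "concentration_mg_per_l", "role")
  if (!all(required %in% header)) {
    stop("Condition file header must contain columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  idx <- match(required, header)
  rows <- fields[-1]
  not_detected <- character()
  tab <- purrr::map_dfr(seq_along(rows), function(i) {
    f <- trimws(rows[[i]])
    if (length(f) < max(idx)) {
      stop("Row ", i + 1, " of ", path, " has too few fields", call. = FALSE)
    }
    tibble::tibble(species = f[idx[1]], conc_raw = f[idx[2]], role = f[idx[3]])
  })
  bad_role <- setdiff(unique(tab$role), CONDITION_ROLES)
  if (length(bad_role)) {
    stop("Unknown role(s) in ", path, ": ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  nd <- toupper(tab$conc_raw) == "ND"
  tab$concentration <- ifelse(nd, 0, suppressWarnings(as.numeric(tab$conc_raw)))
  if (anyNA(tab$concentration)) {
    bad <- which(is.na(tab$concentration))[1]
    stop("Non-numeric concentration '", tab$conc_raw[bad], "' for species ",
         tab$species[bad], " in ", path, call. = FALSE)
  }
  not_detected <- unique(tab$species[nd])

  chemical <- tab$role %in% c("feed", "residual", "product", "amino_acid")
  unknown <- setdiff(unique(tab$species[chemical]), registry$name)
  if (length(unknown)) {
    stop("Species not in registry: ", paste(unknown, collapse = ", "),
         "; extend the registry via compound_registry(extra = ...)",
         call. = FALSE)
  }

  pick <- function(role) {
    sub <- tab[tab$role == role, , drop = FALSE]
    if (!nrow(sub)) return(numeric())
    agg <- tapply(sub$concentration, sub$species, sum)
    stats::setNames(as.numeric(agg), names(agg))
  }
  scalar <- function(role) {
    sub <- tab[tab$role == role, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    sum(sub$concentration)
  }

  aa <- pick("amino_acid")
  profile <- amino_acid_profile(
    aa,
    declared_total_c = if (is.na(meta_num(meta, "aa_total_carbon"))) NULL else
      meta_num(meta, "aa_total_carbon"),
    declared_total_n = if (is.na(meta_num(meta, "aa_total_nitrogen"))) NULL else
      meta_num(meta, "aa_total_nitrogen")
  )
  prot <- scalar("protein")
  chemostat_condition(
    organism = meta$organism %||% "unknown",
    dilution_rate = as.numeric(meta$dilution_rate),
    feed = pick("feed"),
    products = pick("product"),
    residual = pick("residual"),
    cell_carbon = scalar("cell_c"),
    cell_nitrogen = scalar("cell_n"),
    supernatant_protein = if (is.na(prot)) 0 else prot,
    amino_acids = profile,
    feed_nitrogen = meta_num(meta, "feed_nitrogen"),
    not_detected = not_detected
  )
}

#' Write a chemostat condition to a delimited text file
#'
#' Inverse of [read_condition()]; the round trip is lossless, including
#' not-detected flags (written back as `ND`).
#'
#' @param condition A [chemostat_condition()].
#' @param path Output file path.
#' @param delim Field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_condition <- function(condition, path, delim = "\t") {
  stopifnot(inherits(condition, "chemostat_condition"))
  meta <- c(
    paste0("# organism: ", condition$organism),
    paste0("# dilution_rate: ", format(condition$dilution_rate, digits = 15))
  )
  if (!is.na(condition$feed_nitrogen)) {
    meta <- c(meta, paste0("# feed_nitrogen: ",
                           format(condition$feed_nitrogen, digits = 15)))
  }
  if (!is.null(condition$amino_acids$declared_total_c)) {
    meta <- c(meta, paste0("# aa_total_carbon: ",
                           condition$amino_acids$declared_total_c))
  }
  if (!is.null(condition$amino_acids$declared_total_n)) {
    meta <- c(meta, paste0("# aa_total_nitrogen: ",
                           condition$amino_acids$declared_total_n))
  }
  tab <- tidy.chemostat_condition(condition)
  tab <- tab[!(tab$role %in% c("cell_c", "cell_n") & is.na(tab$concentration)), ]
  conc <- ifelse(
    tab$species %in% condition$not_detected & tab$concentration == 0,
    "ND", format(tab$concentration, digits = 15, trim = TRUE)
  )
  lines <- c(
    meta,
    paste("species", "concentration_mg_per_l", "role", sep = delim),
    paste(tab$species, conc, tab$role, sep = delim)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read named reactions from a plain-text equation file
#'
#' One reaction per line, `name: equation`; `#` lines are comments.
#'
#' @param path File path.
#' @return Named list of [reaction()] objects.
#' @examples
#' reactions <- read_reactions(ppiflux_example("pathways.txt"))
#' names(reactions)
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("Reaction line lacks a `name:` prefix: ", ln, call. = FALSE)
    }
    name <- trimws(sub(":.*$", "", ln))
    eq <- trimws(sub("^[^:]*:", "", ln))
    out[[name]] <- parse_reaction(eq, name = name)
  }
  out
}

#' Write a compound registry to a delimited text table
#'
#' @param registry A compound registry tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(
    registry[c("name", "formula", "anion_formula", "class")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Read a compound registry from a delimited text table
#'
#' Molar masses and element counts are rederived from the formulas, so a
#' hand-edited table cannot drift from its own formulas.
#'
#' @param path Path to a table written by [write_registry()] (or with the
#'   same columns).
#' @return A compound registry tibble.
#' @export
read_registry <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           na.strings = "", stringsAsFactors = FALSE)
  rows <- tibble::as_tibble(tab)
  base <- registry_rows()
  extra <- rows[!rows$name %in% base$name, , drop = FALSE]
  reg <- compound_registry(extra = if (nrow(extra)) extra else NULL)
  reg[reg$name %in% rows$name, , drop = FALSE]
}
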