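#' Chemical species registry
#'
#' Table of the substrates and products handled by the balance engine, with
#' molar masses (g/mol), carbon atoms per molecule, and the NAD(P)H
#' stoichiometric coefficients used in the redox bookkeeping: 2 mol NAD(P)H
#' generated per mol of glucose or glycerol consumed through glycolysis, and
#' 4, 2, 1, 0 and 0 mol NAD(P)H required per mol of butanol, butyric acid,
#' isopropanol, acetone and acetic acid produced.  Coefficients carried over
#' directly from that scheme have `redox_status = "core"`; values supplied by
#' this package where the scheme is silent (1,3-propanediol) are flagged
#' `"extrapolated"` and are only used when explicitly enabled.  Sugars other
#' than glucose are registered for carbon accounting only: their generation
#' coefficients are unset and requesting them is an error.
#'
#' @param path Optional path to a registry override in the same tab-separated
#'   format as the bundled table (columns `id`, `aliases` (pipe-separated),
#'   `molar_mass`, `carbon_atoms`, `role`, `nadph_gen_per_mol`,
#'   `nadph_req_per_mol`, `redox_status`).  `NULL` (default) loads the
#'   bundled registry.
#' @return A data frame of class `ib_registry`, one row per species.
#' @examples
#' reg <- species_registry()
#' reg[reg$id == "glucose", ]
#' @export
species_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.ibferm_env$registry)) {
      bundled <- system.file("extdata", "species_registry.tsv",
                             package = "ibferm", mustWork = TRUE)
      .ibferm_env$registry <- load_registry_file(bundled)
    }
    return(.ibferm_env$registry)
  }
  load_registry_file(path)
}

load_registry_file <- function(path) {
  if (!file.exists(path)) {
    ib_validation_error(sprintf("registry file not found: '%s'", path))
  }
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA", colClasses = NA)
  needed <- c("id", "aliases", "molar_mass", "carbon_atoms", "role",
              "nadph_gen_per_mol", "nadph_req_per_mol", "redox_status")
  missing <- setdiff(needed, names(reg))
  if (length(missing)) {
    ib_validation_error(sprintf("registry is missing columns: %s",
                                paste(missing, collapse = ", ")))
  }
  reg$aliases[is.na(reg$aliases)] <- ""
  for (col in c("molar_mass", "nadph_gen_per_mol", "nadph_req_per_mol")) {
    reg[[col]] <- as.numeric(reg[[col]])
  }
  if (any(duplicated(tolower(reg$id)))) {
    ib_validation_error("registry ids must be unique (case-insensitively)")
  }
  if (any(!is.finite(reg$molar_mass) | reg$molar_mass <= 0)) {
    ib_validation_error("registry molar_mass values must be positive")
  }
  if (any(!is.finite(reg$carbon_atoms) | reg$carbon_atoms < 1 |
          reg$carbon_atoms != round(reg$carbon_atoms))) {
    ib_validation_error("registry carbon_atoms must be integers >= 1")
  }
  if (any(!reg$role %in% c("substrate", "product", "both"))) {
    ib_validation_error("registry role must be substrate, product or both")
  }
  class(reg) <- c("ib_registry", "data.frame")
  reg
}

# case-insensitive id/alias resolution; returns canonical id or NA
resolve_species_id <- function(id, registry) {
  key <- tolower(trimws(as.character(id)))
  hit <- match(key, tolower(registry$id))
  if (!is.na(hit)) return(registry$id[hit])
  for (i in seq_len(nrow(registry))) {
    aliases <- tolower(strsplit(registry$aliases[i], "|", fixed = TRUE)[[1]])
    if (key %in% aliases) return(registry$id[i])
  }
  NA_character_
}

#' Look up one chemical species
#'
#' Resolves an id or alias (case-insensitive; e.g. `"BuOH"`, `"IPA"`,
#' `"1,3-PDO"`, `"AA"`, `"BA"`, `"ACT"`) against the registry.
#'
#' @param id Species name or alias.
#' @param registry A registry from [species_registry()]; default the bundled
#'   one.
#' @return A list of class `ib_species` with fields `id`, `molar_mass`,
#'   `carbon_atoms`, `role`, `nadph_gen_per_mol`, `nadph_req_per_mol`,
#'   `redox_status`.
#' @examples
#' get_species("glucose")$nadph_gen_per_mol  # 2
#' get_species("BuOH")$nadph_req_per_mol     # 4
#' @export
get_species <- function(id, registry = species_registry()) {
  canonical <- resolve_species_id(id, registry)
  if (is.na(canonical)) {
    ib_validation_error(sprintf(
      "unknown species '%s'; registered ids: %s",
      id, paste(registry$id, collapse = ", ")))
  }
  row <- registry[registry$id == canonical, , drop = FALSE]
  structure(list(
    id = row$id,
    molar_mass = row$molar_mass,
    carbon_atoms = as.integer(row$carbon_atoms),
    role = row$role,
    nadph_gen_per_mol = row$nadph_gen_per_mol,
    nadph_req_per_mol = row$nadph_req_per_mol,
    redox_status = row$redox_status
  ), class = "ib_species")
}

#' @export
print.ib_species <- function(x, ...) {
  cat(sprintf("<ib_species> %s: %.2f g/mol, %d C, role=%s\n",
              x$id, x$molar_mass, x$carbon_atoms, x$role))
  if (!is.na(x$nadph_gen_per_mol))
    cat(sprintf("  NAD(P)H generated/mol consumed: %g (%s)\n",
                x$nadph_gen_per_mol, x$redox_status))
  if (!is.na(x$nadph_req_per_mol))
    cat(sprintf("  NAD(P)H required/mol produced: %g (%s)\n",
                x$nadph_req_per_mol, x$redox_status))
  invisible(x)
}

#' Convert a mass concentration to millimolar
#'
#' `to_millimolar()` converts g/L to mM using the registry molar mass;
#' `carbon_millimolar()` further multiplies by the carbon atoms per molecule
#' to give mM of carbon, the normalisation basis for per-carbon-mole
#' metrics and carbon recovery.
#'
#' @param conc Concentration(s) in g/L, non-negative.
#' @param species Species id/alias, or an `ib_species`.
#' @param registry Registry to resolve against.
#' @return Numeric vector, mM (or mM carbon).
#' @examples
#' to_millimolar(21.85, "glucose")      # 121.28 mM
#' carbon_millimolar(21.85, "glucose")  # 727.69 mM C
#' @export
to_millimolar <- function(conc, species, registry = species_registry()) {
  sp <- if (inherits(species, "ib_species")) species else
    get_species(species, registry)
  conc <- as.numeric(conc)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    ib_validation_error(sprintf(
      "concentration for '%s' must be finite and >= 0", sp$id))
  }
  conc * 1000 / sp$molar_mass
}

#' @rdname to_millimolar
#' @export
carbon_millimolar <- function(conc, species, registry = species_registry()) {
  sp <- if (inherits(species, "ib_species")) species else
    get_species(species, registry)
  to_millimolar(conc, sp, registry) * sp$carbon_atoms
}

# coefficient accessors shared by the balance engine ------------------------

nadph_gen_coef <- function(species, registry = species_registry(),
                           allow_extrapolated = FALSE) {
  sp <- if (inherits(species, "ib_species")) species else
    get_species(species, registry)
  if (is.na(sp$nadph_gen_per_mol)) {
    ib_computation_error(sprintf(
      "no NAD(P)H generation coefficient registered for substrate '%s'",
      sp$id))
  }
  if (identical(sp$redox_status, "extrapolated") && !allow_extrapolated) {
    ib_computation_error(sprintf(
      "NAD(P)H generation coefficient for '%s' is extrapolated; set allow_extrapolated = TRUE to use it",
      sp$id))
  }
  sp$nadph_gen_per_mol
}

nadph_req_coef <- function(species, registry = species_registry(),
                           allow_extrapolated = FALSE) {
  sp <- if (inherits(species, "ib_species")) species else
    get_species(species, registry)
  if (is.na(sp$nadph_req_per_mol)) {
    ib_computation_error(sprintf(
      "no NAD(P)H requirement coefficient registered for product '%s'",
      sp$id))
  }
  if (identical(sp$redox_status, "extrapolated") && !allow_extrapolated) {
    ib_computation_error(sprintf(
      "NAD(P)H requirement coefficient for '%s' is extrapolated; set allow_extrapolated = TRUE to use it",
      sp$id))
  }
  sp$nadph_req_per_mol
}
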