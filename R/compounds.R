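#' Compound registry
#'
#' The molecular species handled by the balancing machinery: fermentable
#' sugars, their anhydro (polymer-monomer) forms, the organic fermentation
#' products as free acids, the fermentation gases, water, and microbial
#' biomass expressed per carbon as the empirical pseudo-formula
#' CH2N0.25O0.5 (25.53 g per C-mol).
#'
#' The registry ships as a plain-text table
#' (`system.file("extdata", "compounds.csv", package = "fermbalance")`)
#' with columns `name`, `carbon`, `hydrogen`, `oxygen`, `nitrogen`,
#' `molar_mass`; a user-edited copy can be supplied through `path` to
#' probe alternative constants.
#'
#' @param path Optional path to a registry CSV; defaults to the shipped one.
#' @return A data frame with one row per compound and columns `name`,
#'   `carbon`, `hydrogen`, `oxygen`, `nitrogen` (atoms per molecule; the
#'   biomass pseudo-formula has fractional counts) and `molar_mass` (g/mol).
#' @examples
#' compound_registry()
#' @export
compound_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compounds.csv", package = "fermbalance")
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "carbon", "hydrogen", "oxygen", "nitrogen", "molar_mass")
  missing <- setdiff(needed, names(reg))
  if (length(missing) > 0L) {
    stop("compound registry lacks column(s): ", paste(missing, collapse = ", "))
  }
  validate_registry(reg)
  reg
}

# standard atomic weights, g/mol
.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

validate_registry <- function(reg) {
  if (anyDuplicated(reg$name)) stop("duplicate compound names in registry")
  atoms <- as.matrix(reg[, c("carbon", "hydrogen", "oxygen", "nitrogen")])
  if (any(atoms < 0)) stop("negative atom counts in registry")
  if (any(reg$molar_mass <= 0)) stop("non-positive molar mass in registry")
  # integer formulas must be mass-consistent; the per-carbon biomass
  # pseudo-formula is exempt from the integrality expectation
  integral <- apply(atoms, 1L, function(a) all(abs(a - round(a)) < 1e-9))
  formula_mass <- atoms %*% .atomic_mass[c("C", "H", "O", "N")]
  bad <- integral & abs(formula_mass - reg$molar_mass) > 0.5
  if (any(bad)) {
    stop(
      "molar mass disagrees with formula for: ",
      paste(reg$name[bad], collapse = ", ")
    )
  }
  invisible(reg)
}

#' Look up a compound by name
#'
#' @param name Compound name as listed in the registry (e.g. `"glucose"`,
#'   `"anhydrohexose"`, `"biomass"`).
#' @param registry A registry data frame from [compound_registry()].
#' @return A one-row data frame (class `fb_compound`) with the compound's
#'   elemental composition and molar mass.
#' @examples
#' compound("glucose")$molar_mass
#' @export
compound <- function(name, registry = compound_registry()) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown compound: '", name, "'; registry has: ",
         paste(registry$name, collapse = ", "))
  }
  out <- registry[i, , drop = FALSE]
  class(out) <- c("fb_compound", "data.frame")
  out
}

#' Molar concentration of a mass loading
#'
#' Converts a mass concentration (g/l) of a registered compound to mM.
#' For anhydro sugars this is the molar currency used throughout:
#' 10 g/l of pure cellulose corresponds to 61.68 mM anhydroglucose
#' (glucose equivalents on full hydrolysis).
#'
#' @param mass Mass concentration in g/l; must be non-negative.
#' @param compound_name Name in the registry, or an `fb_compound` row.
#' @param registry Registry data frame; see [compound_registry()].
#' @return Concentration in mM.
#' @examples
#' molar_concentration(10, "glucose")       # 55.51 mM
#' molar_concentration(10, "anhydrohexose") # 61.68 mM
#' @export
molar_concentration <- function(mass, compound_name,
                                registry = compound_registry()) {
  if (any(!is.finite(mass)) || any(mass < 0)) {
    stop("mass must be finite and non-negative (g/l)")
  }
  cmp <- if (inherits(compound_name, "fb_compound")) {
    compound_name
  } else {
    compound(compound_name, registry)
  }
  mass / cmp$molar_mass * 1000
}

#' Degree of reduction (available electrons per mole)
#'
#' Available-electron content of a compound relative to the
#' CO2/H2O/NH3 reference state: gamma = 4 C + H - 2 O - 3 N.
#' Glucose carries 24 electron equivalents per mole, ethanol and lactate
#' 12, acetate 8, H2 2; CO2 and water carry none. Biomass on the
#' per-carbon formula CH2N0.25O0.5 carries 4.25.
#'
#' @param compound_name Name in the registry, or an `fb_compound` row.
#' @param registry Registry data frame.
#' @return Electron equivalents per mole (per C-mol for biomass).
#' @examples
#' degree_of_reduction("glucose") # 24
#' degree_of_reduction("biomass") # 4.25
#' @export
degree_of_reduction <- function(compound_name, registry = compound_registry()) {
  cmp <- if (inherits(compound_name, "fb_compound")) {
    compound_name
  } else {
    compound(compound_name, registry)
  }
  4 * cmp$carbon + cmp$hydrogen - 2 * cmp$oxygen - 3 * cmp$nitrogen
}

#' @export
print.fb_compound <- function(x, ...) {
  cat(sprintf(
    "<compound> %s: C%.3g H%.3g O%.3g N%.3g, %.2f g/mol, gamma = %.4g\n",
    x$name, x$carbon, x$hydrogen, x$oxygen, x$nitrogen, x$molar_mass,
    4 * x$carbon + x$hydrogen - 2 * x$oxygen - 3 * x$nitrogen
  ))
  invisible(x)
}
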