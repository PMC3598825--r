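#' Cell biomass as dry weight and carbon
#'
#' Interconverts cell dry weight (g/l) and cell carbon (mM carbon) via the
#' empirical per-carbon cell formula CH2N0.25O0.5, 25.53 g per C-mol.
#' Either measurement direction is accepted; supplying one fills in the
#' other.
#'
#' @param dry_weight Cell dry weight in g/l.
#' @param carbon Cell carbon in mM carbon (C-mmol/l).
#' @param registry Compound registry; the biomass molar mass is taken from
#'   its `biomass` entry.
#' @return A `cell_biomass` object with both fields populated.
#' @examples
#' cell_biomass(carbon = 14.4)$dry_weight # 0.37 g/l
#' @export
cell_biomass <- function(dry_weight = NULL, carbon = NULL,
                         registry = compound_registry()) {
  if (is.null(dry_weight) && is.null(carbon)) {
    stop("supply dry_weight (g/l) or carbon (mM carbon)")
  }
  if (is.null(carbon)) carbon <- carbon_from_cdw(dry_weight, registry)
  if (is.null(dry_weight)) dry_weight <- cdw_from_carbon(carbon, registry)
  if (carbon < 0 || dry_weight < 0) stop("cell biomass must be non-negative")
  structure(list(dry_weight = dry_weight, carbon = carbon),
            class = "cell_biomass")
}

#' @rdname cell_biomass
#' @export
cdw_from_carbon <- function(carbon, registry = compound_registry()) {
  if (any(!is.finite(carbon)) || any(carbon < 0)) {
    stop("cell carbon must be finite and non-negative (mM carbon)")
  }
  carbon * compound("biomass", registry)$molar_mass / 1000
}

#' @rdname cell_biomass
#' @export
carbon_from_cdw <- function(dry_weight, registry = compound_registry()) {
  if (any(!is.finite(dry_weight)) || any(dry_weight < 0)) {
    stop("cell dry weight must be finite and non-negative (g/l)")
  }
  dry_weight / compound("biomass", registry)$molar_mass * 1000
}

#' @export
print.cell_biomass <- function(x, ...) {
  cat(sprintf("<cell biomass> %.3f g/l = %.2f mM carbon (CH2N0.25O0.5)\n",
              x$dry_weight, x$carbon))
  invisible(x)
}

new_balance_result <- function(kind, substrate_total, breakdown) {
  product_total <- sum(breakdown)
  structure(list(
    kind = kind,
    substrate_total = substrate_total,
    product_total = product_total,
    recovery = product_total / substrate_total * 100,
    breakdown = breakdown
  ), class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  unit <- if (x$kind == "carbon") "mM carbon" else "electron meq/l"
  cat(sprintf("<%s balance>\n  substrate  %8.1f %s\n", x$kind,
              x$substrate_total, unit))
  for (nm in names(x$breakdown)) {
    cat(sprintf("  %-10s %8.1f\n", nm, x$breakdown[[nm]]))
  }
  cat(sprintf("  products   %8.1f %s\n  recovery   %8.1f %%\n",
              x$product_total, unit, x$recovery))
  invisible(x)
}

# shared walk over the measured species of a record
.balance <- function(consumed_sugars, profile, cells, weight_fun, kind) {
  stopifnot(inherits(consumed_sugars, "sugar_equivalents"),
            inherits(profile, "product_profile"))
  sub <- unclass(consumed_sugars)
  substrate_total <- sum(vapply(
    names(sub), function(nm) sub[[nm]] * weight_fun(nm), numeric(1)
  ))
  if (substrate_total <= 0) {
    if (total_organic(profile) > 0) {
      stop("recovery undefined: products present but no substrate consumed")
    }
    stop("recovery undefined: no substrate consumed")
  }
  breakdown <- c(
    ethanol = profile$ethanol * weight_fun("ethanol"),
    acetate = profile$acetate * weight_fun("acetate"),
    lactate = profile$lactate * weight_fun("lactate")
  )
  if (!is.na(profile$co2)) {
    breakdown <- c(breakdown, co2 = profile$co2 * weight_fun("co2"))
  }
  if (!is.na(profile$h2)) {
    breakdown <- c(breakdown, h2 = profile$h2 * weight_fun("h2"))
  }
  cell_c <- if (!is.null(cells)) cells$carbon else profile$cell_carbon
  if (!is.null(cell_c) && !is.na(cell_c)) {
    breakdown <- c(breakdown, cells = cell_c * weight_fun("biomass"))
  }
  new_balance_result(kind, substrate_total, breakdown)
}

#' Carbon recovery balance
#'
#' Percent of consumed substrate carbon recovered in measured products
#' plus cells. Substrate carbon is the consumed sugar equivalents weighted
#' by carbon atoms (6 per hexose unit, 5 per pentose unit); product carbon
#' is 2 C/mol for ethanol and acetate, 3 for lactate, 1 for CO2, and the
#' cell carbon directly. A recovery near 100% indicates a closed balance.
#'
#' @param consumed_sugars Consumed substrate as a `sugar_equivalents`
#'   object (mM monomer equivalents).
#' @param profile A `product_profile`; species measured as NA are omitted
#'   from the product side (not treated as zero).
#' @param cells Optional [cell_biomass()]; if absent, the profile's
#'   `cell_carbon` field is used when present.
#' @param registry Compound registry supplying elemental compositions.
#' @return A `balance_result` with fields `substrate_total`,
#'   `product_total`, `recovery` (%) and per-species `breakdown`.
#' @examples
#' carbon_recovery(
#'   sugars(glucose = 30.6),
#'   product_profile(5.5, 21.9, 35.3, co2 = 8.8),
#'   cell_biomass(carbon = 9.7)
#' )
#' @export
carbon_recovery <- function(consumed_sugars, profile, cells = NULL,
                            registry = compound_registry()) {
  weight <- function(nm) compound(nm, registry)$carbon
  .balance(consumed_sugars, profile, cells, weight, "carbon")
}

#' Available-electron recovery balance
#'
#' Same accounting as [carbon_recovery()] but in electron equivalents:
#' each species is weighted by its degree of reduction (glucose 24,
#' xylose 20, ethanol and lactate 12, acetate 8, H2 2, CO2 0, cell
#' carbon 4.25 per C-mol under an NH3 nitrogen source).
#'
#' @inheritParams carbon_recovery
#' @return A `balance_result` in electron milliequivalents per litre.
#' @examples
#' electron_recovery(
#'   sugars(glucose = 30.6),
#'   product_profile(5.5, 21.9, 35.3, h2 = 20.8),
#'   cell_biomass(carbon = 9.7)
#' )
#' @export
electron_recovery <- function(consumed_sugars, profile, cells = NULL,
                              registry = compound_registry()) {
  weight <- function(nm) degree_of_reduction(nm, registry)
  .balance(consumed_sugars, profile, cells, weight, "electron")
}
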