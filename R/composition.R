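#' Biomass composition
#'
#' Mass-fraction description of a (pretreated) lignocellulosic substrate,
#' as produced by standard structural-carbohydrate compositional analysis.
#' Carbohydrate polymers are the hexosans glucan, galactan and mannan and
#' the pentosans xylan and arabinan; lignin fractions and ash are carried
#' along as informational fields and take no part in sugar accounting.
#'
#' @param glucan,xylan,galactan,arabinan,mannan Polymer mass fractions of
#'   dry substrate, each in \[0, 1\].
#' @param lignin_acid_soluble,lignin_acid_insoluble,ash Informational mass
#'   fractions, each in \[0, 1\].
#' @param name Optional substrate name.
#' @return An object of class `biomass_composition`.
#' @examples
#' washed_poplar <- biomass_composition(
#'   glucan = 0.581, xylan = 0.001, galactan = 0.002,
#'   lignin_acid_soluble = 0.027, lignin_acid_insoluble = 0.348,
#'   ash = 0.001, name = "washed poplar"
#' )
#' sugar_equivalents(washed_poplar, loading = 2.9)
#' @export
biomass_composition <- function(glucan = 0, xylan = 0, galactan = 0,
                                arabinan = 0, mannan = 0,
                                lignin_acid_soluble = 0,
                                lignin_acid_insoluble = 0, ash = 0,
                                name = NULL) {
  fr <- c(
    glucan = glucan, xylan = xylan, galactan = galactan,
    arabinan = arabinan, mannan = mannan,
    lignin_acid_soluble = lignin_acid_soluble,
    lignin_acid_insoluble = lignin_acid_insoluble, ash = ash
  )
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("every mass fraction must lie in [0, 1]")
  }
  # small analytical over-closure is tolerated
  if (sum(fr) > 1 + 0.02) {
    stop(sprintf("mass fractions sum to %.3f, exceeding 1 + 0.02", sum(fr)))
  }
  structure(list(fractions = fr, name = name), class = "biomass_composition")
}

.hexosans <- c(glucan = "glucose", galactan = "galactose", mannan = "mannose")
.pentosans <- c(xylan = "xylose", arabinan = "arabinose")

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass composition>",
      if (!is.null(x$name)) paste0(" ", x$name), "\n", sep = "")
  fr <- x$fractions[x$fractions > 0]
  if (length(fr) == 0L) {
    cat("  (all fractions zero)\n")
  } else {
    for (nm in names(fr)) cat(sprintf("  %-22s %5.1f %%\n", nm, 100 * fr[[nm]]))
  }
  invisible(x)
}

#' Sugar equivalents of a substrate loading
#'
#' Converts a dry-mass loading of a substrate into the monosaccharide
#' molar concentrations obtainable on complete hydrolysis. Polymer mass
#' is divided by the anhydro-monomer molar mass — 162.14 g/mol for
#' hexosans, 132.11 g/mol for pentosans — because the condensed monomer,
#' not the free sugar, is the polymer's repeating unit.
#'
#' @param composition A [biomass_composition()].
#' @param loading Substrate loading in g/l dry mass; non-negative.
#' @param registry Compound registry (see [compound_registry()]); the
#'   anhydrohexose/anhydropentose masses are taken from it so they can be
#'   overridden in one place.
#' @return A `sugar_equivalents` object: named numeric vector of mM for
#'   glucose, galactose, mannose (hexoses) and xylose, arabinose (pentoses).
#' @examples
#' poplar <- biomass_composition(glucan = 0.581, xylan = 0.001,
#'                               galactan = 0.002)
#' sugar_equivalents(poplar, 2.9) # 10.4 mM glucose equivalents
#' @export
sugar_equivalents <- function(composition, loading,
                              registry = compound_registry()) {
  if (!inherits(composition, "biomass_composition")) {
    stop("composition must be a biomass_composition object")
  }
  if (!is.finite(loading) || loading < 0) {
    stop("loading must be finite and non-negative (g/l)")
  }
  hex_mass <- compound("anhydrohexose", registry)$molar_mass
  pen_mass <- compound("anhydropentose", registry)$molar_mass
  fr <- composition$fractions
  eq <- c(
    vapply(names(.hexosans), function(p) loading * fr[[p]] / hex_mass * 1000,
           numeric(1)),
    vapply(names(.pentosans), function(p) loading * fr[[p]] / pen_mass * 1000,
           numeric(1))
  )
  names(eq) <- c(unname(.hexosans), unname(.pentosans))
  new_sugar_equivalents(eq)
}

#' Construct sugar equivalents directly
#'
#' For defined-sugar media (e.g. 55.51 mM glucose from 10 g/l) or
#' measured consumption, build the equivalents vector without going
#' through a polymer composition.
#'
#' @param glucose,galactose,mannose,xylose,arabinose Concentrations in mM.
#' @return A `sugar_equivalents` object.
#' @examples
#' sugars(glucose = 55.51)
#' @export
sugars <- function(glucose = 0, galactose = 0, mannose = 0,
                   xylose = 0, arabinose = 0) {
  new_sugar_equivalents(c(
    glucose = glucose, galactose = galactose, mannose = mannose,
    xylose = xylose, arabinose = arabinose
  ))
}

new_sugar_equivalents <- function(x) {
  stopifnot(setequal(names(x),
                     c("glucose", "galactose", "mannose", "xylose", "arabinose")))
  x <- x[c("glucose", "galactose", "mannose", "xylose", "arabinose")]
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("sugar equivalents must be finite and non-negative (mM)")
  }
  structure(x, class = "sugar_equivalents")
}

#' Hexose and pentose class totals
#'
#' @param x A `sugar_equivalents` object.
#' @return Total mM over the class members.
#' @export
hexoses <- function(x) {
  stopifnot(inherits(x, "sugar_equivalents"))
  sum(unclass(x)[c("glucose", "galactose", "mannose")])
}

#' @rdname hexoses
#' @export
pentoses <- function(x) {
  stopifnot(inherits(x, "sugar_equivalents"))
  sum(unclass(x)[c("xylose", "arabinose")])
}

#' @export
print.sugar_equivalents <- function(x, ...) {
  cat("<sugar equivalents, mM>\n")
  v <- unclass(x)
  for (nm in names(v)) {
    if (v[[nm]] > 0) cat(sprintf("  %-10s %8.2f\n", nm, v[[nm]]))
  }
  cat(sprintf("  hexoses %.2f mM, pentoses %.2f mM\n", hexoses(x), pentoses(x)))
  invisible(x)
}

#' Consumed glucose equivalents from substrate weight loss
#'
#' For washed polymeric substrates where no pentose is released, the
#' measured loss of dry weight is attributed to cellulose consumption and
#' converted to anhydroglucose equivalents (162.14 g/mol).
#'
#' @param weight_loss Dry-weight loss in g/l; non-negative.
#' @param registry Compound registry.
#' @return Consumed glucose equivalents in mM.
#' @examples
#' consumed_equivalents_from_weight_loss(4.12) # 25.4 mM
#' @export
consumed_equivalents_from_weight_loss <- function(weight_loss,
                                                  registry = compound_registry()) {
  if (any(!is.finite(weight_loss)) || any(weight_loss < 0)) {
    stop("weight loss must be finite and non-negative (g/l)")
  }
  molar_concentration(weight_loss, "anhydrohexose", registry)
}

#' Read a substrate composition table
#'
#' Reads a delimited long-format table with columns `substrate`,
#' `polymer`, `fraction` (or `percent`, divided by 100 at parse time)
#' into a named list of [biomass_composition()] objects.
#'
#' @param path CSV file path.
#' @return Named list of `biomass_composition` objects.
#' @examples
#' path <- system.file("extdata", "substrates.csv", package = "fermbalance")
#' comps <- read_composition_table(path)
#' names(comps)
#' @export
read_composition_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("substrate", "polymer") %in% names(tab))) {
    stop("composition table needs columns substrate, polymer, fraction|percent")
  }
  if ("fraction" %in% names(tab)) {
    tab$fraction <- as.numeric(tab$fraction)
  } else if ("percent" %in% names(tab)) {
    tab$fraction <- as.numeric(tab$percent) / 100
  } else {
    stop("composition table needs a fraction or percent column")
  }
  known <- c(names(.hexosans), names(.pentosans),
             "lignin_acid_soluble", "lignin_acid_insoluble", "ash")
  bad <- setdiff(unique(tab$polymer), known)
  if (length(bad) > 0L) {
    stop("unknown polymer name(s): ", paste(bad, collapse = ", "))
  }
  lapply(split(tab, tab$substrate), function(rows) {
    args <- as.list(rows$fraction)
    names(args) <- rows$polymer
    args$name <- rows$substrate[1L]
    do.call(biomass_composition, args)
  })
}
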