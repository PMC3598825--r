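#' Product profile of a fermentation
#'
#' End-point concentrations of the organic fermentation products, with
#' optional gases and cell carbon for balance work. Concentrations are mM;
#' cell carbon is mM carbon (C-mmol/l).
#'
#' @param ethanol,acetate,lactate Organic product concentrations, mM.
#' @param co2,h2 Optional gas concentrations, mM (NA when unmeasured).
#' @param cell_carbon Optional cell carbon, mM carbon.
#' @return A `product_profile` object.
#' @examples
#' p <- product_profile(ethanol = 8.8, acetate = 19.9, lactate = 11.0)
#' total_organic(p)
#' @export
product_profile <- function(ethanol, acetate, lactate,
                            co2 = NA_real_, h2 = NA_real_,
                            cell_carbon = NA_real_) {
  x <- c(ethanol = ethanol, acetate = acetate, lactate = lactate,
         co2 = co2, h2 = h2, cell_carbon = cell_carbon)
  measured <- x[!is.na(x)]
  if (any(!is.finite(measured)) || any(measured < 0)) {
    stop("product concentrations must be finite and non-negative (mM)")
  }
  if (anyNA(x[c("ethanol", "acetate", "lactate")])) {
    stop("ethanol, acetate and lactate are required")
  }
  structure(as.list(x), class = "product_profile")
}

#' @rdname product_profile
#' @param profile A `product_profile`.
#' @return `total_organic()`: ethanol + acetate + lactate in mM.
#' @export
total_organic <- function(profile) {
  stopifnot(inherits(profile, "product_profile"))
  profile$ethanol + profile$acetate + profile$lactate
}

#' @export
print.product_profile <- function(x, ...) {
  cat(sprintf("<product profile> ethanol %.1f, acetate %.1f, lactate %.1f mM",
              x$ethanol, x$acetate, x$lactate))
  if (!is.na(x$co2)) cat(sprintf(", CO2 %.1f", x$co2))
  if (!is.na(x$h2)) cat(sprintf(", H2 %.1f", x$h2))
  if (!is.na(x$cell_carbon)) cat(sprintf(", cells %.1f mM-C", x$cell_carbon))
  cat(sprintf("\n  total organics %.1f mM, ratio %s\n",
              total_organic(x), format_ratio(normalized_ratio(x))))
  invisible(x)
}

#' Theoretical yield constants
#'
#' Maximum mol of ethanol+acetate+lactate formable per mol of sugar under
#' mixed-acid fermentation: 2.0 per hexose (each C6 yields two
#' pyruvate-equivalent C3 units) and 1.67 per pentose (the conventionally
#' rounded 5/3). The pentose factor is stored as the rounded 1.67, the
#' value used in published capacity sums, so printed capacities are
#' reproduced exactly.
#'
#' @param hexose_factor mol products per mol C6 sugar.
#' @param pentose_factor mol products per mol C5 sugar.
#' @return A `yield_constants` object.
#' @export
yield_constants <- function(hexose_factor = 2.0, pentose_factor = 1.67) {
  if (hexose_factor <= 0 || pentose_factor <= 0) {
    stop("yield factors must be positive")
  }
  structure(list(hexose_factor = hexose_factor,
                 pentose_factor = pentose_factor),
            class = "yield_constants")
}

#' Theoretical product capacity of a sugar pool
#'
#' Upper bound on total ethanol+acetate+lactate formable from the given
#' sugar equivalents: `hexose_factor * sum(hexoses) +
#' pentose_factor * sum(pentoses)`.
#'
#' @param sugars A `sugar_equivalents` object.
#' @param constants A [yield_constants()] object.
#' @return Capacity in mM.
#' @examples
#' product_capacity(sugars(glucose = 10.4, galactose = 0.03, xylose = 0.02))
#' @export
product_capacity <- function(sugars, constants = yield_constants()) {
  stopifnot(inherits(sugars, "sugar_equivalents"),
            inherits(constants, "yield_constants"))
  constants$hexose_factor * hexoses(sugars) +
    constants$pentose_factor * pentoses(sugars)
}

#' Substrate utilization as percent of theoretical capacity
#'
#' Fraction of the theoretical product capacity realized as measured
#' organic products. Uses only ethanol+acetate+lactate, matching the
#' capacity definition; gases and cells do not enter.
#'
#' @param profile A `product_profile`, or the total organic products in mM.
#' @param capacity Theoretical capacity in mM; must be positive.
#' @return Utilization in percent.
#' @examples
#' utilization_percent(36.4, 150.3) # 24.2
#' @export
utilization_percent <- function(profile, capacity) {
  total <- if (inherits(profile, "product_profile")) {
    total_organic(profile)
  } else {
    profile
  }
  if (!is.finite(capacity) || capacity <= 0) {
    stop("capacity must be positive; utilization is undefined otherwise")
  }
  if (total < 0) stop("total organic products must be non-negative")
  total / capacity * 100
}

#' Ethanol mole percent of the organic products
#'
#' @param profile A `product_profile`.
#' @return Ethanol as mol% of ethanol+acetate+lactate.
#' @examples
#' ethanol_mole_percent(product_profile(1, 1.1, 0.7)) # 35.7
#' @export
ethanol_mole_percent <- function(profile) {
  mole_percents(profile)[["ethanol"]]
}

#' @rdname ethanol_mole_percent
#' @return `mole_percents()`: named vector of ethanol/acetate/lactate mol%.
#' @export
mole_percents <- function(profile) {
  stopifnot(inherits(profile, "product_profile"))
  total <- total_organic(profile)
  if (total <= 0) {
    stop("mole fractions are undefined for a profile with no organic products")
  }
  c(ethanol = profile$ethanol, acetate = profile$acetate,
    lactate = profile$lactate) / total * 100
}

#' Ethanol-normalized product ratio
#'
#' The conventional `1 : acetate/ethanol : lactate/ethanol` molar ratio.
#' When ethanol is zero the ratio is renormalized to the largest component
#' and flagged (`attr(, "reference")` names the component used).
#'
#' @param profile A `product_profile`.
#' @return Numeric triple `(ethanol, acetate, lactate)` relative to the
#'   reference component (first element 1 when ethanol > 0), with
#'   attribute `reference`. Use [format_ratio()] for one-decimal display.
#' @examples
#' format_ratio(normalized_ratio(product_profile(8.8, 19.9, 11.0)))
#' # "1 : 2.3 : 1.3"
#' @export
normalized_ratio <- function(profile) {
  stopifnot(inherits(profile, "product_profile"))
  v <- c(ethanol = profile$ethanol, acetate = profile$acetate,
         lactate = profile$lactate)
  if (v[["ethanol"]] > 0) {
    ref <- "ethanol"
  } else {
    if (all(v == 0)) stop("cannot normalize an all-zero profile")
    ref <- names(v)[which.max(v)]
  }
  structure(v / v[[ref]], reference = ref)
}

#' @rdname normalized_ratio
#' @param ratio A ratio from [normalized_ratio()].
#' @param digits Decimals for the non-reference components.
#' @export
format_ratio <- function(ratio, digits = 1) {
  ref <- attr(ratio, "reference")
  parts <- vapply(seq_along(ratio), function(i) {
    if (names(ratio)[i] == ref) "1"
    else formatC(round_half_up(ratio[[i]], digits), format = "f",
                 digits = digits)
  }, character(1))
  out <- paste(parts, collapse = " : ")
  if (!identical(ref, "ethanol")) out <- paste0(out, " (rel. ", ref, ")")
  out
}

#' Fold change of a product between two profiles
#'
#' @param test,reference `product_profile` objects.
#' @param field Which product to compare (default `"ethanol"`).
#' @return `test[field] / reference[field]`.
#' @examples
#' mono <- product_profile(2.7, 21.4, 9.0)
#' co   <- product_profile(10.3, 18.6, 11.8)
#' fold_change(co, mono) # 3.8-fold more ethanol
#' @export
fold_change <- function(test, reference,
                        field = c("ethanol", "acetate", "lactate")) {
  field <- match.arg(field)
  stopifnot(inherits(test, "product_profile"),
            inherits(reference, "product_profile"))
  ref <- reference[[field]]
  if (ref <= 0) stop("reference ", field, " must be positive for a fold change")
  test[[field]] / ref
}

#' Round half away from zero
#'
#' Display rounding for reported tables: 1.25 rounds to 1.3 at one
#' decimal, unlike base `round()`'s round-half-even. Applied only at
#' report time; all internal arithmetic keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # guard against values like 12.499999999 that are 12.5 at full precision
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
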