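#' Strain parameters for the fermentation simulator
#'
#' A black-box description of a strain's catabolism. Consumed sugar
#' carbon is split between cell biomass (`biomass_fraction`) and
#' catabolism; catabolized carbon is processed at the C3
#' (pyruvate-equivalent) level — two units per hexose, 5/3 per pentose —
#' and each unit becomes ethanol, acetate or lactate according to
#' `product_split`. Ethanol and acetate units release one CO2 each;
#' H2 is set by exact electron closure. The hexose/pentose theoretical
#' yield factors 2.0 and 5/3 thus emerge from the mechanism rather than
#' being imposed.
#'
#' @param name Strain name.
#' @param product_split Numeric triple (ethanol, acetate, lactate) of
#'   mole fractions of catabolized C3 units; non-negative, summing to 1.
#' @param biomass_fraction Fraction of consumed substrate carbon diverted
#'   to cells, in \[0, 0.15\].
#' @param consumption_extent Fraction of the available (in-scope) sugar
#'   equivalents the strain consumes, in \[0, 1\].
#' @param scope `"cellulolytic"` (hydrolyzes polymeric substrates and
#'   ferments the released sugars) or `"saccharolytic"` (soluble sugars
#'   only).
#' @return A `strain_params` object.
#' @examples
#' strain_params("cellulolytic-lactogenic",
#'               product_split = c(0.08, 0.55, 0.37),
#'               biomass_fraction = 0.05, scope = "cellulolytic")
#' @export
strain_params <- function(name, product_split,
                          biomass_fraction = 0.05,
                          consumption_extent = 1,
                          scope = c("cellulolytic", "saccharolytic")) {
  scope <- match.arg(scope)
  product_split <- unname(as.numeric(product_split))
  if (length(product_split) != 3L || any(product_split < 0) ||
      abs(sum(product_split) - 1) > 1e-9) {
    stop("product_split must be three non-negative fractions summing to 1")
  }
  if (biomass_fraction < 0 || biomass_fraction > 0.15) {
    stop("biomass_fraction must lie in [0, 0.15]")
  }
  if (consumption_extent < 0 || consumption_extent > 1) {
    stop("consumption_extent must lie in [0, 1]")
  }
  structure(list(
    name = name,
    product_split = stats::setNames(product_split,
                                    c("ethanol", "acetate", "lactate")),
    biomass_fraction = biomass_fraction,
    consumption_extent = consumption_extent,
    scope = scope
  ), class = "strain_params")
}

#' Measurement noise model
#'
#' Multiplicative Gaussian noise, independent across analytes and
#' truncated at zero: each measured quantity x is reported as
#' `x * max(0, 1 + N(0, relative_sd))`. The seed is an explicit field;
#' the generator uses it locally and restores the caller's RNG state.
#'
#' @param relative_sd Relative standard deviation (dimensionless, >= 0).
#' @param seed Integer seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(relative_sd = 0, seed = 1L) {
  if (relative_sd < 0) stop("relative_sd must be non-negative")
  structure(list(relative_sd = relative_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# run code under a seed, then restore the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.sugar_carbons <- c(glucose = 6, galactose = 6, mannose = 6,
                    xylose = 5, arabinose = 5)
.sugar_electrons <- c(glucose = 24, galactose = 24, mannose = 24,
                      xylose = 20, arabinose = 20)

#' Closure gases for an organic product split
#'
#' Given the organic products formed per mol of sugar and the carbon
#' diverted to cells, returns the CO2 and H2 that close the carbon and
#' available-electron balances exactly. Per mol hexose (24 electron
#' equivalents, 6 carbons):
#' CO2 carries the carbon not found in organics or cells, and
#' `2 H2 = 24 - 12 e - 8 a - 12 l - 4.25 biomass_c`. The pentose analog
#' uses 20 electrons and 5 carbons.
#'
#' @param split Numeric triple `(e, a, l)`: mol ethanol, acetate, lactate
#'   formed per mol sugar; non-negative with `e + a + l` at most the
#'   sugar's C3-unit count (2 for hexose, 5/3 for pentose).
#' @param biomass_c C-mol of cell carbon formed per mol sugar.
#' @param sugar `"hexose"` or `"pentose"`.
#' @param gamma_biomass Degree of reduction of cell carbon (default 4.25,
#'   the CH2N0.25O0.5 value under an NH3 nitrogen source).
#' @return Named numeric `c(co2, h2)` in mol per mol sugar.
#' @examples
#' closure_gases(c(0, 2, 0)) # glucose -> 2 acetate + 2 CO2 + 4 H2
#' @export
closure_gases <- function(split, biomass_c = 0,
                          sugar = c("hexose", "pentose"),
                          gamma_biomass = 4.25) {
  sugar <- match.arg(sugar)
  split <- unname(as.numeric(split))
  if (length(split) != 3L || any(split < 0)) {
    stop("split must be three non-negative values (ethanol, acetate, lactate)")
  }
  if (biomass_c < 0) stop("biomass_c must be non-negative")
  n_c <- if (sugar == "hexose") 6 else 5
  n_e <- if (sugar == "hexose") 24 else 20
  e <- split[1L]; a <- split[2L]; l <- split[3L]
  co2 <- n_c - (2 * e + 2 * a + 3 * l) - biomass_c
  if (co2 < -1e-9) {
    stop("infeasible split: organic products and cells exceed substrate carbon")
  }
  h2 <- (n_e - 12 * e - 8 * a - 12 * l - gamma_biomass * biomass_c) / 2
  if (h2 < -1e-9) {
    stop("infeasible split: electron deficit (products more reduced than substrate)")
  }
  c(co2 = max(co2, 0), h2 = max(h2, 0))
}

# noise-free outcome of one or two strains on a sugar pool:
# consumed equivalents, pooled products, gases from closure, cell carbon
.simulate_core <- function(strains, available, share, gamma_biomass) {
  strains <- if (inherits(strains, "strain_params")) list(strains) else strains
  if (length(strains) < 1L || length(strains) > 2L) {
    stop("supply one or two strain_params objects")
  }
  av <- unclass(available)
  cellulolytic <- vapply(strains, function(s) s$scope == "cellulolytic",
                         logical(1))
  # overall extent: the hydrolyzing strain gates polymeric substrates;
  # on defined sugars the more voracious partner sets the extent
  extent <- if (any(cellulolytic)) {
    max(vapply(strains[cellulolytic], `[[`, numeric(1), "consumption_extent"))
  } else {
    max(vapply(strains, `[[`, numeric(1), "consumption_extent"))
  }
  consumed <- av * extent
  shares <- if (length(strains) == 2L) c(share, 1 - share) else 1
  totals <- c(ethanol = 0, acetate = 0, lactate = 0)
  cell_c <- 0
  co2 <- 0
  h2 <- 0
  for (k in seq_along(strains)) {
    s <- strains[[k]]
    for (nm in names(consumed)) {
      n_sugar <- consumed[[nm]] * shares[k]
      if (n_sugar <= 0) next
      n_c <- .sugar_carbons[[nm]]
      f <- s$biomass_fraction
      units <- n_c * (1 - f) / 3            # C3 units catabolized
      org <- units * s$product_split        # mol products per mol sugar
      bio_c <- n_c * f
      gas <- closure_gases(org, bio_c,
                           sugar = if (n_c == 6) "hexose" else "pentose",
                           gamma_biomass = gamma_biomass)
      totals <- totals + n_sugar * org
      cell_c <- cell_c + n_sugar * bio_c
      co2 <- co2 + n_sugar * gas[["co2"]]
      h2 <- h2 + n_sugar * gas[["h2"]]
    }
  }
  list(consumed = new_sugar_equivalents(consumed), totals = totals,
       cell_carbon = cell_c, co2 = co2, h2 = h2, extent = extent)
}

.apply_noise <- function(x, relative_sd) {
  if (relative_sd == 0 || is.na(x)) return(x)
  x * max(0, 1 + stats::rnorm(1L, 0, relative_sd))
}

#' Generate a stoichiometrically closed fermentation outcome
#'
#' Simulates the end point of a mono- or co-culture fermentation.
#' Consumption equals the gating strain's `consumption_extent` times the
#' available equivalents; in a co-culture the cellulolytic partner
#' hydrolyzes the polymer and the released sugars are partitioned by
#' `share`. Products follow each strain's split, CO2 and H2 come from
#' exact carbon/electron closure ([closure_gases()]), so at zero noise
#' both [carbon_recovery()] and [electron_recovery()] of the record are
#' exactly 100%. In `uncontrolled-flask` mode consumption additionally
#' halts once the organic acids (acetate + lactate) reach
#' `acid_threshold`, emulating self-acidification of unbuffered cultures.
#'
#' Measurement noise is multiplicative truncated-Gaussian per analyte;
#' the record is deterministic for a fixed `noise$seed`.
#'
#' @param strains A `strain_params` object or list of two.
#' @param substrate A [biomass_composition()] (polymeric substrate) or a
#'   `sugar_equivalents` pool at the stated loading (defined sugars).
#' @param loading Substrate loading in g/l dry mass (for compositions);
#'   for a defined sugar pool, the corresponding mass is derived from the
#'   pool itself and `loading` may be omitted.
#' @param noise A [noise_model()].
#' @param ph_mode Culture mode; acidification gating applies only to
#'   `"uncontrolled-flask"`.
#' @param share Fraction of each released sugar taken by the first strain
#'   of a co-culture (default 0.5; the partition is not measurable from
#'   end points, so it is an explicit model knob).
#' @param acid_threshold Organic-acid concentration (mM acetate+lactate)
#'   at which an unbuffered flask culture stalls.
#' @param gamma_biomass Degree of reduction of cell carbon.
#' @param id Record id.
#' @param replicate Replicate index.
#' @param registry Compound registry.
#' @return A one-row `experiment_records` data frame; attribute `truth`
#'   holds the noise-free quantities (consumed equivalents, products,
#'   pooled split) for parameter-recovery work.
#' @examples
#' cellu <- strain_params("cellu", c(0.08, 0.55, 0.37),
#'                        scope = "cellulolytic")
#' rec <- generate_outcome(cellu, biomass_composition(glucan = 1), 10,
#'                         noise = noise_model(0, seed = 7),
#'                         ph_mode = "ph-controlled-fermentor")
#' rec$ethanol_mM
#' @export
generate_outcome <- function(strains, substrate, loading = NULL,
                             noise = noise_model(0, 1L),
                             ph_mode = c("uncontrolled-flask",
                                         "buffered-flask",
                                         "ph-controlled-fermentor"),
                             share = 0.5, acid_threshold = 30,
                             gamma_biomass = 4.25,
                             id = "sim", replicate = 1L,
                             registry = compound_registry()) {
  ph_mode <- match.arg(ph_mode)
  strains <- if (inherits(strains, "strain_params")) list(strains) else strains
  if (share < 0 || share > 1) stop("share must lie in [0, 1]")
  polymeric <- inherits(substrate, "biomass_composition")
  if (polymeric) {
    if (is.null(loading)) stop("loading (g/l) required for a composition")
    available <- sugar_equivalents(substrate, loading, registry)
    if (!any(vapply(strains, function(s) s$scope == "cellulolytic",
                    logical(1)))) {
      stop("no strain in the culture can hydrolyze a polymeric substrate")
    }
    substrate_name <- if (!is.null(substrate$name)) substrate$name else "biomass"
  } else if (inherits(substrate, "sugar_equivalents")) {
    available <- substrate
    if (is.null(loading)) {
      av <- unclass(available)
      masses <- vapply(names(av), function(nm) {
        av[[nm]] * compound(nm, registry)$molar_mass / 1000
      }, numeric(1))
      loading <- sum(masses)
    }
    nz <- names(unclass(available))[unclass(available) > 0]
    substrate_name <- if (length(nz) == 1L) nz else "defined sugars"
  } else {
    stop("substrate must be a biomass_composition or sugar_equivalents")
  }

  core <- .simulate_core(strains, available, share, gamma_biomass)
  # unbuffered flasks stall once the acids acidify the medium; products
  # scale with consumption, so capping is a uniform rescale
  if (ph_mode == "uncontrolled-flask") {
    acids <- core$totals[["acetate"]] + core$totals[["lactate"]]
    if (acids > acid_threshold) {
      scale <- acid_threshold / acids
      core$consumed <- new_sugar_equivalents(unclass(core$consumed) * scale)
      core$totals <- core$totals * scale
      core$cell_carbon <- core$cell_carbon * scale
      core$co2 <- core$co2 * scale
      core$h2 <- core$h2 * scale
    }
  }

  # consumed dry mass, to report a final substrate weight
  cons <- unclass(core$consumed)
  consumed_mass <- if (polymeric) {
    hex <- compound("anhydrohexose", registry)$molar_mass
    pen <- compound("anhydropentose", registry)$molar_mass
    sum(cons[c("glucose", "galactose", "mannose")]) * hex / 1000 +
      sum(cons[c("xylose", "arabinose")]) * pen / 1000
  } else {
    sum(vapply(names(cons), function(nm) {
      cons[[nm]] * compound(nm, registry)$molar_mass / 1000
    }, numeric(1)))
  }

  cdw <- cdw_from_carbon(core$cell_carbon, registry)
  truth <- list(
    consumed = core$consumed, products = core$totals,
    co2 = core$co2, h2 = core$h2, cell_carbon = core$cell_carbon,
    split = core$totals / sum(core$totals)
  )
  rsd <- noise$relative_sd
  meas <- with_seed(noise$seed, {
    list(
      ethanol = .apply_noise(core$totals[["ethanol"]], rsd),
      acetate = .apply_noise(core$totals[["acetate"]], rsd),
      lactate = .apply_noise(core$totals[["lactate"]], rsd),
      co2 = .apply_noise(core$co2, rsd),
      h2 = .apply_noise(core$h2, rsd),
      cdw = .apply_noise(cdw, rsd),
      final = min(loading, .apply_noise(loading - consumed_mass, rsd))
    )
  })
  rec <- data.frame(
    id = id,
    strains = paste(vapply(strains, `[[`, character(1), "name"),
                    collapse = "+"),
    substrate = substrate_name,
    loading_g_l = loading, ph_mode = ph_mode,
    substrate_final_g_l = meas$final,
    ethanol_mM = meas$ethanol, acetate_mM = meas$acetate,
    lactate_mM = meas$lactate, co2_mM = meas$co2, h2_mM = meas$h2,
    cdw_g_l = meas$cdw, replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  rec <- validate_experiments(rec, origin = "generated record")
  attr(rec, "truth") <- truth
  rec
}

#' Generate a fermentation time course
#'
#' Product concentrations over time for the same model as
#' [generate_outcome()]: substrate consumption follows a logistic
#' trajectory (anchored at zero consumption at t = 0) and products
#' accumulate in proportion to consumption with fixed splits. The final
#' time point reproduces [generate_outcome()] under the same seed. In
#' `uncontrolled-flask` mode the trajectory plateaus where the organic
#' acids reach `acid_threshold`. Interior points receive independent
#' multiplicative noise; at zero noise all product curves are monotone
#' non-decreasing.
#'
#' @inheritParams generate_outcome
#' @param n_points Number of time points (>= 2), from 0 to `t_end`.
#' @param t_end Final time, h.
#' @param k Logistic steepness (1/h).
#' @param t_mid Logistic midpoint, h.
#' @return A `timecourse` object: data frame with columns `time_h`,
#'   `ethanol_mM`, `acetate_mM`, `lactate_mM`, `co2_mM`, `h2_mM`,
#'   `cdw_g_l`, `substrate_g_l`; attribute `endpoint` is the
#'   [generate_outcome()] record.
#' @examples
#' cellu <- strain_params("cellu", c(0.08, 0.55, 0.37),
#'                        scope = "cellulolytic")
#' tc <- generate_timecourse(cellu, biomass_composition(glucan = 1), 10,
#'                           n_points = 5,
#'                           ph_mode = "ph-controlled-fermentor")
#' tc$ethanol_mM
#' @export
generate_timecourse <- function(strains, substrate, loading = NULL,
                                n_points = 13L,
                                noise = noise_model(0, 1L),
                                ph_mode = c("uncontrolled-flask",
                                            "buffered-flask",
                                            "ph-controlled-fermentor"),
                                share = 0.5, acid_threshold = 30,
                                gamma_biomass = 4.25,
                                t_end = 144, k = 0.08, t_mid = 60,
                                id = "sim", registry = compound_registry()) {
  ph_mode <- match.arg(ph_mode)
  if (n_points < 2L) stop("n_points must be at least 2")
  endpoint <- generate_outcome(
    strains, substrate, loading, noise = noise, ph_mode = ph_mode,
    share = share, acid_threshold = acid_threshold,
    gamma_biomass = gamma_biomass, id = id, registry = registry
  )
  truth <- attr(endpoint, "truth")
  times <- seq(0, t_end, length.out = n_points)
  # logistic rise anchored to 0 at t = 0 and 1 at t_end
  raw <- 1 / (1 + exp(-k * (times - t_mid)))
  g <- (raw - raw[1L]) / (raw[n_points] - raw[1L])
  rsd <- noise$relative_sd
  interior_noise <- with_seed(noise$seed + 1L, {
    matrix(pmax(0, 1 + stats::rnorm(6L * n_points, 0, rsd)),
           nrow = n_points)
  })
  curve <- function(final_truth, col, final_meas) {
    x <- final_truth * g * interior_noise[, col]
    x[n_points] <- final_meas
    x[1L] <- 0
    x
  }
  loading_g_l <- endpoint$loading_g_l
  consumed_mass <- loading_g_l - endpoint$substrate_final_g_l
  tc <- data.frame(
    time_h = times,
    ethanol_mM = curve(truth$products[["ethanol"]], 1L, endpoint$ethanol_mM),
    acetate_mM = curve(truth$products[["acetate"]], 2L, endpoint$acetate_mM),
    lactate_mM = curve(truth$products[["lactate"]], 3L, endpoint$lactate_mM),
    co2_mM = curve(truth$co2, 4L, endpoint$co2_mM),
    h2_mM = curve(truth$h2, 5L, endpoint$h2_mM),
    cdw_g_l = curve(cdw_from_carbon(truth$cell_carbon, registry), 6L,
                    endpoint$cdw_g_l)
  )
  tc$substrate_g_l <- loading_g_l - g * consumed_mass
  tc$substrate_g_l[n_points] <- endpoint$substrate_final_g_l
  if (any(diff(tc$time_h) <= 0)) stop("times must be strictly increasing")
  structure(tc, endpoint = endpoint,
            class = c("timecourse", "data.frame"))
}

#' Estimate product-split parameters from a record
#'
#' The mole fractions of the organic product pool are the natural
#' estimator of a strain's (or pooled co-culture's) product split: on a
#' noise-free record they reproduce the generating split exactly, and
#' under symmetric multiplicative noise their average across replicates
#' is unbiased.
#'
#' @param record A one-row `experiment_records` data frame, a
#'   `product_profile`, or anything with `ethanol_mM`/`acetate_mM`/
#'   `lactate_mM` columns.
#' @return Named numeric `(ethanol, acetate, lactate)` summing to 1.
#' @export
estimate_split <- function(record) {
  v <- if (inherits(record, "product_profile")) {
    c(record$ethanol, record$acetate, record$lactate)
  } else {
    c(record$ethanol_mM[1L], record$acetate_mM[1L], record$lactate_mM[1L])
  }
  total <- sum(v)
  if (!is.finite(total) || total <= 0) {
    stop("cannot estimate a split from a record with no organic products")
  }
  stats::setNames(v / total, c("ethanol", "acetate", "lactate"))
}
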