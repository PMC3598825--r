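# shared fixtures built in code

fixture_path <- function(name) {
  system.file("extdata", name, package = "fermbalance")
}

washed_poplar <- biomass_composition(
  glucan = 0.581, xylan = 0.001, galactan = 0.002,
  lignin_acid_soluble = 0.027, lignin_acid_insoluble = 0.348, ash = 0.001,
  name = "washed poplar"
)

raw_poplar <- biomass_composition(
  glucan = 0.424, xylan = 0.116, galactan = 0.018,
  arabinan = 0.022, mannan = 0.026,
  lignin_acid_soluble = 0.054, lignin_acid_insoluble = 0.250, ash = 0.005,
  name = "raw poplar"
)

pure_cellulose <- biomass_composition(glucan = 1, name = "avicel")

# strain pairings used across generator tests: a lactogenic cellulolytic
# strain and an ethanologenic saccharolytic partner
cellu_strain <- function(extent = 0.9) {
  strain_params("cellu", c(0.082, 0.646, 0.272),
                biomass_fraction = 0.05, consumption_extent = extent,
                scope = "cellulolytic")
}
thermo_strain <- function(extent = 0.95) {
  strain_params("thermo", c(0.683, 0.061, 0.256),
                biomass_fraction = 0.05, consumption_extent = extent,
                scope = "saccharolytic")
}

# random feasible strain parameters (electron-feasible by construction:
# acetate-leaning splits keep H2 non-negative at any biomass fraction)
random_strain <- function(scope = "cellulolytic") {
  repeat {
    w <- stats::runif(3)
    split <- w / sum(w)
    f <- stats::runif(1, 0, 0.1)
    org <- 2 * (1 - f) * split
    ok <- tryCatch({
      closure_gases(org, 6 * f)
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      return(strain_params("rnd", split, biomass_fraction = f,
                           consumption_extent = stats::runif(1, 0.3, 1),
                           scope = scope))
    }
  }
}

# independent brute-force accounting used as the balance oracle: walk
# every molecule of a record and add up per-atom contributions, without
# touching the per-species formula-weight path
atom_count_balance <- function(consumed, profile, cell_carbon, what) {
  atoms <- list(
    glucose = c(C = 6, H = 12, O = 6, N = 0),
    galactose = c(C = 6, H = 12, O = 6, N = 0),
    mannose = c(C = 6, H = 12, O = 6, N = 0),
    xylose = c(C = 5, H = 10, O = 5, N = 0),
    arabinose = c(C = 5, H = 10, O = 5, N = 0),
    ethanol = c(C = 2, H = 6, O = 1, N = 0),
    acetate = c(C = 2, H = 4, O = 2, N = 0),
    lactate = c(C = 3, H = 6, O = 3, N = 0),
    co2 = c(C = 1, H = 0, O = 2, N = 0),
    h2 = c(C = 0, H = 2, O = 0, N = 0),
    cells = c(C = 1, H = 2, O = 0.5, N = 0.25)
  )
  value <- function(a) {
    if (what == "carbon") a[["C"]]
    else 4 * a[["C"]] + a[["H"]] - 2 * a[["O"]] - 3 * a[["N"]]
  }
  subs <- unclass(consumed)
  substrate <- sum(vapply(names(subs), function(nm) {
    subs[[nm]] * value(atoms[[nm]])
  }, numeric(1)))
  conc <- c(ethanol = profile$ethanol, acetate = profile$acetate,
            lactate = profile$lactate)
  if (!is.na(profile$co2)) conc <- c(conc, co2 = profile$co2)
  if (!is.na(profile$h2)) conc <- c(conc, h2 = profile$h2)
  if (!is.na(cell_carbon)) conc <- c(conc, cells = cell_carbon)
  products <- sum(vapply(names(conc), function(nm) {
    conc[[nm]] * value(atoms[[nm]])
  }, numeric(1)))
  products / substrate * 100
}
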