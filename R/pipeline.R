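#' Batch sugar-equivalents table
#'
#' Runs the composition -> equivalents -> capacity conversion for a batch
#' of substrates and loadings, the first stage of the analysis pipeline.
#'
#' @param compositions Path to a composition CSV (see
#'   [read_composition_table()]) or a named list of
#'   [biomass_composition()] objects.
#' @param loadings Data frame with columns `substrate`, `loading_g_l`
#'   (or path to such a CSV). Substrates must appear in `compositions`.
#' @param constants [yield_constants()] for the capacity column.
#' @param out Optional output CSV path.
#' @return Data frame with one row per substrate/loading: the five sugar
#'   equivalents (mM), hexose/pentose totals and theoretical product
#'   capacity (mM).
#' @examples
#' comps <- system.file("extdata", "substrates.csv", package = "fermbalance")
#' run_equivalents(comps, data.frame(substrate = "washed_poplar",
#'                                   loading_g_l = 2.9))
#' @export
run_equivalents <- function(compositions, loadings,
                            constants = yield_constants(), out = NULL) {
  comps <- if (is.character(compositions)) {
    read_composition_table(compositions)
  } else {
    compositions
  }
  if (is.character(loadings)) {
    loadings <- utils::read.csv(loadings, stringsAsFactors = FALSE)
  }
  if (nrow(loadings) == 0L) {
    empty <- data.frame(substrate = character(0), loading_g_l = numeric(0))
    return(empty)
  }
  stopifnot(all(c("substrate", "loading_g_l") %in% names(loadings)))
  unknown <- setdiff(loadings$substrate, names(comps))
  if (length(unknown) > 0L) {
    stop("no composition for substrate(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(loadings)), function(i) {
    eq <- sugar_equivalents(comps[[loadings$substrate[i]]],
                            loadings$loading_g_l[i])
    v <- unclass(eq)
    data.frame(
      substrate = loadings$substrate[i],
      loading_g_l = loadings$loading_g_l[i],
      glucose_mM = v[["glucose"]], galactose_mM = v[["galactose"]],
      mannose_mM = v[["mannose"]], xylose_mM = v[["xylose"]],
      arabinose_mM = v[["arabinose"]],
      hexoses_mM = hexoses(eq), pentoses_mM = pentoses(eq),
      capacity_mM = product_capacity(eq, constants),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) write_report(res, out, "csv")
  res
}

#' Full analysis of experiment records
#'
#' Wires the pipeline stages together: reads records, summarizes product
#' statistics per condition group, derives theoretical capacities and
#' utilization where a substrate composition (or a defined sugar) is
#' known, and computes carbon/electron balances where final substrate
#' masses are recorded.
#'
#' @param records An `experiment_records` data frame or CSV path.
#' @param compositions Optional composition table (path or list) for
#'   polymeric substrates; records whose `substrate` is a registered
#'   defined sugar (e.g. `"glucose"`) need no composition.
#' @param constants [yield_constants()].
#' @param registry Compound registry.
#' @param out_dir Optional directory to write `summary.csv` and
#'   `balances.csv` into.
#' @return List with elements `summary` (see [summarize_experiments()]),
#'   `balances` (see [balance_experiments()]; NULL when no final masses
#'   are recorded) and `capacities` (named vector used for utilization).
#' @export
run_analysis <- function(records, compositions = NULL,
                         constants = yield_constants(),
                         registry = compound_registry(), out_dir = NULL) {
  recs <- if (is.character(records)) read_experiments(records) else records
  stopifnot(inherits(recs, "experiment_records"))
  comps <- if (is.character(compositions)) {
    read_composition_table(compositions)
  } else {
    compositions
  }
  # theoretical capacity per substrate at each recorded loading
  caps <- numeric(0)
  for (i in seq_len(nrow(recs))) {
    sub <- recs$substrate[i]
    if (sub %in% names(caps)) next
    eq <- if (!is.null(comps) && sub %in% names(comps)) {
      sugar_equivalents(comps[[sub]], recs$loading_g_l[i], registry)
    } else if (sub %in% names(.sugar_carbons)) {
      pool <- stats::setNames(as.list(rep(0, 5)), names(.sugar_carbons))
      pool[[sub]] <- molar_concentration(recs$loading_g_l[i], sub, registry)
      do.call(sugars, pool)
    } else {
      NULL
    }
    if (!is.null(eq)) {
      caps[sub] <- product_capacity(eq, constants)
    }
  }
  summary <- summarize_experiments(recs, capacities = caps)
  balances <- if (all(!is.na(recs$substrate_final_g_l))) {
    balance_experiments(recs, registry)
  } else {
    NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(summary, file.path(out_dir, "summary.csv"), "csv")
    if (!is.null(balances)) {
      write_report(balances, file.path(out_dir, "balances.csv"), "csv")
    }
  }
  list(summary = summary, balances = balances, capacities = caps)
}

#' Run a simulation scenario
#'
#' Reads a scenario definition (YAML), generates the requested replicate
#' records with [generate_outcome()], writes them in the standard record
#' schema, and performs a closure self-check: at zero noise every
#' generated record must show exactly 100% carbon and electron recovery.
#'
#' The scenario file defines `strains` (name, product_split,
#' biomass_fraction, consumption_extent, scope), `substrate` (either
#' `composition` polymer fractions with `loading_g_l`, or a defined
#' `sugar` with `loading_g_l`), `cultures` (each a vector of strain names
#' to grow together), and optional `noise_relative_sd`, `replicates`,
#' `ph_mode`, `share`, `acid_threshold`.
#'
#' @param scenario Path to a scenario YAML, or an equivalent list.
#' @param seed Integer seed; replicate r of culture c uses a seed derived
#'   deterministically from it.
#' @param out_dir Optional directory for `records.csv` and
#'   `selfcheck.csv`.
#' @return List with `records` (an `experiment_records` data frame),
#'   `selfcheck` (per-record carbon/electron recovery), and
#'   `fold_change` (ethanol fold change of each co-culture over the
#'   first monoculture sharing its substrate, where applicable).
#' @examples
#' scen <- system.file("extdata", "scenario.yaml", package = "fermbalance")
#' sim <- run_simulation(scen, seed = 1)
#' sim$selfcheck$carbon_recovery_pct
#' @export
run_simulation <- function(scenario, seed = 1L, out_dir = NULL) {
  sc <- if (is.character(scenario)) yaml::read_yaml(scenario) else scenario
  strains <- lapply(sc$strains, function(s) {
    strain_params(
      name = s$name, product_split = unlist(s$product_split),
      biomass_fraction = s$biomass_fraction %||% 0.05,
      consumption_extent = s$consumption_extent %||% 1,
      scope = s$scope %||% "cellulolytic"
    )
  })
  names(strains) <- vapply(strains, `[[`, character(1), "name")
  substrate <- if (!is.null(sc$substrate$composition)) {
    do.call(biomass_composition,
            c(sc$substrate$composition, name = sc$substrate$name %||% "substrate"))
  } else if (!is.null(sc$substrate$sugar)) {
    pool <- stats::setNames(as.list(rep(0, 5)), names(.sugar_carbons))
    pool[[sc$substrate$sugar]] <-
      molar_concentration(sc$substrate$loading_g_l, sc$substrate$sugar)
    do.call(sugars, pool)
  } else {
    stop("scenario substrate must give a composition or a sugar")
  }
  loading <- sc$substrate$loading_g_l
  rsd <- sc$noise_relative_sd %||% 0
  nrep <- sc$replicates %||% 1L
  ph_mode <- sc$ph_mode %||% "uncontrolled-flask"
  recs <- list()
  for (ci in seq_along(sc$cultures)) {
    members <- strains[unlist(sc$cultures[[ci]])]
    if (anyNA(names(members))) stop("culture refers to an undefined strain")
    for (r in seq_len(nrep)) {
      rec <- generate_outcome(
        unname(members), substrate, loading,
        noise = noise_model(rsd, seed = seed + 1000L * ci + r),
        ph_mode = ph_mode, share = sc$share %||% 0.5,
        acid_threshold = sc$acid_threshold %||% 30,
        id = sprintf("sim-%02d-%02d", ci, r), replicate = r
      )
      recs[[length(recs) + 1L]] <- rec
    }
  }
  records <- validate_experiments(do.call(rbind, recs), origin = "simulation")
  # closure self-check on noise-free twins of every record
  checks <- lapply(recs, function(rec) {
    truth <- attr(rec, "truth")
    prof <- product_profile(
      truth$products[["ethanol"]], truth$products[["acetate"]],
      truth$products[["lactate"]], co2 = truth$co2, h2 = truth$h2,
      cell_carbon = truth$cell_carbon
    )
    data.frame(
      id = rec$id,
      carbon_recovery_pct = carbon_recovery(truth$consumed, prof)$recovery,
      electron_recovery_pct = electron_recovery(truth$consumed, prof)$recovery,
      stringsAsFactors = FALSE
    )
  })
  selfcheck <- do.call(rbind, checks)
  # ethanol fold change of multi-strain cultures over the first monoculture
  fold <- NULL
  mono <- which(!grepl("+", records$strains, fixed = TRUE))
  multi <- which(grepl("+", records$strains, fixed = TRUE))
  if (length(mono) > 0L && length(multi) > 0L) {
    ref <- mean(records$ethanol_mM[mono])
    if (ref > 0) {
      by_culture <- split(records$ethanol_mM[multi], records$strains[multi])
      fold <- vapply(by_culture, function(x) mean(x) / ref, numeric(1))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(records, file.path(out_dir, "records.csv"), "csv")
    write_report(selfcheck, file.path(out_dir, "selfcheck.csv"), "csv")
  }
  list(records = records, selfcheck = selfcheck, fold_change = fold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
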