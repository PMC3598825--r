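#' Read fermentation experiment records
#'
#' Reads a CSV of end-point fermentation records, one row per
#' replicate-condition, and validates every row. The schema is fixed:
#' `id, strains, substrate, loading_g_l, ph_mode, substrate_final_g_l,
#' ethanol_mM, acetate_mM, lactate_mM, co2_mM, h2_mM, cdw_g_l, replicate`.
#' `strains` holds one name (monoculture) or two joined by `+`
#' (co-culture). Concentrations are mM; substrate loading and cell dry
#' weight are g/l. Gas and cell columns may be empty — unmeasured, not
#' zero. `ph_mode` is one of `uncontrolled-flask`, `buffered-flask`,
#' `ph-controlled-fermentor`.
#'
#' @param path CSV file path.
#' @return A data frame of class `experiment_records`, with a
#'   `group` column identifying the replicate group
#'   (culture x substrate x loading).
#' @examples
#' path <- system.file("extdata", "table2_experiments.csv",
#'                     package = "fermbalance")
#' recs <- read_experiments(path)
#' nrow(recs)
#' @export
read_experiments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_experiments(df, origin = path)
}

.record_schema <- c(
  "id", "strains", "substrate", "loading_g_l", "ph_mode",
  "substrate_final_g_l", "ethanol_mM", "acetate_mM", "lactate_mM",
  "co2_mM", "h2_mM", "cdw_g_l", "replicate"
)

.ph_modes <- c("uncontrolled-flask", "buffered-flask",
               "ph-controlled-fermentor")

#' Validate a data frame of experiment records
#'
#' @param df Data frame in the standard record schema.
#' @param origin Label used in error messages (file name).
#' @return The validated `experiment_records` data frame.
#' @export
validate_experiments <- function(df, origin = "records") {
  missing <- setdiff(.record_schema, names(df))
  if (length(missing) > 0L) {
    stop(origin, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    out <- df[, .record_schema, drop = FALSE]
    out$group <- character(0)
    class(out) <- c("experiment_records", "data.frame")
    return(out)
  }
  num_cols <- c("loading_g_l", "substrate_final_g_l", "ethanol_mM",
                "acetate_mM", "lactate_mM", "co2_mM", "h2_mM", "cdw_g_l")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  problems <- character(0)
  note <- function(i, msg) {
    # +1 for the header line of the file
    problems <<- c(problems, sprintf("row %d (line %d): %s", i, i + 1L, msg))
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!nzchar(r$strains)) note(i, "culture (strains) is empty")
    if (is.na(r$loading_g_l) || r$loading_g_l <= 0) {
      note(i, "loading_g_l must be positive")
    }
    if (!r$ph_mode %in% .ph_modes) {
      note(i, paste0("unknown ph_mode '", r$ph_mode, "'"))
    }
    if (!is.na(r$substrate_final_g_l) &&
        (r$substrate_final_g_l < 0 ||
         r$substrate_final_g_l > r$loading_g_l + 1e-9)) {
      note(i, "substrate_final_g_l must lie in [0, loading_g_l]")
    }
    for (cl in c("ethanol_mM", "acetate_mM", "lactate_mM",
                 "co2_mM", "h2_mM", "cdw_g_l")) {
      if (!is.na(r[[cl]]) && r[[cl]] < 0) {
        note(i, paste0(cl, " is negative (", r[[cl]], ")"))
      }
    }
    if (anyNA(r[c("ethanol_mM", "acetate_mM", "lactate_mM")])) {
      note(i, "ethanol_mM, acetate_mM and lactate_mM are required")
    }
  }
  if (length(problems) > 0L) {
    stop(origin, ": invalid record(s):\n  ",
         paste(problems, collapse = "\n  "))
  }
  df$group <- paste(df$strains, df$substrate, df$loading_g_l, sep = " | ")
  class(df) <- c("experiment_records", "data.frame")
  df
}

#' Product profile of one record row
#'
#' @param record One row of an `experiment_records` data frame.
#' @return A [product_profile()] with cell carbon filled in from the
#'   dry weight when measured.
#' @export
record_profile <- function(record) {
  cc <- if (!is.na(record$cdw_g_l)) carbon_from_cdw(record$cdw_g_l) else NA_real_
  product_profile(
    ethanol = record$ethanol_mM, acetate = record$acetate_mM,
    lactate = record$lactate_mM, co2 = record$co2_mM, h2 = record$h2_mM,
    cell_carbon = cc
  )
}

.mean_sd <- function(x) {
  c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
}

#' Summarize replicated experiment records
#'
#' Aggregates records per condition group (culture x substrate x loading).
#' Statistics are computed per replicate first and then aggregated as
#' mean +/- sample standard deviation, so a group's ethanol mol% is the
#' mean of the replicate mol% values, not the mol% of the mean profile.
#' Single-replicate groups report NA standard deviations.
#'
#' When `capacities` supplies a theoretical product capacity (mM) for a
#' substrate, the group's utilization percent is reported as well.
#'
#' @param records An `experiment_records` data frame.
#' @param capacities Optional named numeric vector: substrate name ->
#'   theoretical capacity in mM at the record's loading.
#' @return A data frame with one row per group: replicate count, product
#'   means and sds, total products, ethanol mol%, the
#'   ethanol-normalized ratio string, and utilization where available.
#' @examples
#' recs <- read_experiments(system.file("extdata", "table2_experiments.csv",
#'                                      package = "fermbalance"))
#' summarize_experiments(recs)[, c("strains", "substrate", "total_mean")]
#' @export
summarize_experiments <- function(records, capacities = NULL) {
  stopifnot(inherits(records, "experiment_records"))
  if (nrow(records) == 0L) stop("no records to summarize")
  groups <- split(records, records$group)
  # preserve input block order rather than alphabetical split order
  groups <- groups[unique(records$group)]
  rows <- lapply(groups, function(g) {
    profs <- lapply(seq_len(nrow(g)), function(i) record_profile(g[i, ]))
    totals <- vapply(profs, total_organic, numeric(1))
    molpct <- vapply(profs, ethanol_mole_percent, numeric(1))
    eth <- .mean_sd(g$ethanol_mM); ace <- .mean_sd(g$acetate_mM)
    lac <- .mean_sd(g$lactate_mM); tot <- .mean_sd(totals)
    mp <- .mean_sd(molpct)
    mean_prof <- product_profile(eth[["mean"]], ace[["mean"]], lac[["mean"]])
    out <- data.frame(
      strains = g$strains[1L], substrate = g$substrate[1L],
      loading_g_l = g$loading_g_l[1L], ph_mode = g$ph_mode[1L],
      n = nrow(g),
      ethanol_mean = eth[["mean"]], ethanol_sd = eth[["sd"]],
      acetate_mean = ace[["mean"]], acetate_sd = ace[["sd"]],
      lactate_mean = lac[["mean"]], lactate_sd = lac[["sd"]],
      ratio = format_ratio(normalized_ratio(mean_prof)),
      total_mean = tot[["mean"]], total_sd = tot[["sd"]],
      ethanol_molpct_mean = mp[["mean"]], ethanol_molpct_sd = mp[["sd"]],
      utilization_pct = NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(capacities) && g$substrate[1L] %in% names(capacities)) {
      out$utilization_pct <-
        utilization_percent(tot[["mean"]], capacities[[g$substrate[1L]]])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Carbon and electron balances of experiment records
#'
#' Computes per-group fermentation balances in the style of a
#' fermentation-balance table: consumed substrate equivalents, product
#' and cell carbon, and carbon/electron recovery percentages. Consumption
#' is derived from the substrate columns: for `substrate = "glucose"`
#' the initial-minus-final mass is converted with the glucose molar mass;
#' for any other (polymeric) substrate the dry-weight loss is attributed
#' to cellulose and converted to anhydroglucose equivalents. Groups
#' lacking gas or cell measurements report those species as absent, and
#' the recovery reflects only measured species.
#'
#' @param records An `experiment_records` data frame; rows must carry
#'   `substrate_final_g_l`.
#' @param registry Compound registry.
#' @return Data frame with one row per group: consumed equivalents (mM),
#'   mean products, cell carbon, substrate/product carbon totals, and
#'   `carbon_recovery_pct` / `electron_recovery_pct`.
#' @examples
#' recs <- read_experiments(system.file("extdata", "table3_experiments.csv",
#'                                      package = "fermbalance"))
#' balance_experiments(recs)[, c("strains", "substrate",
#'                               "carbon_recovery_pct")]
#' @export
balance_experiments <- function(records, registry = compound_registry()) {
  stopifnot(inherits(records, "experiment_records"))
  if (anyNA(records$substrate_final_g_l)) {
    stop("balance requires substrate_final_g_l on every record")
  }
  groups <- split(records, records$group)
  groups <- groups[unique(records$group)]
  rows <- lapply(groups, function(g) {
    m <- function(cl) mean(g[[cl]])
    consumed_mass <- m("loading_g_l") - m("substrate_final_g_l")
    consumed <- if (g$substrate[1L] == "glucose") {
      sugars(glucose = molar_concentration(consumed_mass, "glucose", registry))
    } else {
      sugars(glucose = consumed_equivalents_from_weight_loss(consumed_mass,
                                                             registry))
    }
    cc <- if (all(!is.na(g$cdw_g_l))) carbon_from_cdw(m("cdw_g_l")) else NA_real_
    prof <- product_profile(
      ethanol = m("ethanol_mM"), acetate = m("acetate_mM"),
      lactate = m("lactate_mM"),
      co2 = if (all(!is.na(g$co2_mM))) m("co2_mM") else NA_real_,
      h2 = if (all(!is.na(g$h2_mM))) m("h2_mM") else NA_real_,
      cell_carbon = cc
    )
    cb <- carbon_recovery(consumed, prof, registry = registry)
    eb <- electron_recovery(consumed, prof, registry = registry)
    data.frame(
      strains = g$strains[1L], substrate = g$substrate[1L],
      loading_g_l = g$loading_g_l[1L], n = nrow(g),
      consumed_g_l = consumed_mass,
      consumed_equiv_mM = unclass(consumed)[["glucose"]],
      ethanol_mM = prof$ethanol, acetate_mM = prof$acetate,
      lactate_mM = prof$lactate, co2_mM = prof$co2, h2_mM = prof$h2,
      cell_carbon_mM = cc,
      substrate_carbon_mM = cb$substrate_total,
      product_carbon_mM = cb$product_total,
      carbon_recovery_pct = cb$recovery,
      electron_recovery_pct = eb$recovery,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report table
#'
#' Writes summary or balance rows as CSV (lossless round-trip at full
#' precision) or as a markdown pipe table with numeric columns rounded
#' half-up to one decimal for display.
#'
#' @param rows Non-empty data frame of report rows.
#' @param path Output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("report rows must be a non-empty data frame")
  }
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    disp <- rows
    for (cl in names(disp)) {
      if (is.numeric(disp[[cl]])) {
        disp[[cl]] <- formatC(round_half_up(disp[[cl]], 1), format = "f",
                              digits = 1)
        disp[[cl]][disp[[cl]] %in% c("NA", "NaN")] <- ""
      }
    }
    header <- paste0("| ", paste(names(disp), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(disp)), collapse = "|"), "|")
    body <- apply(disp, 1L, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    writeLines(c(header, sep, body), path)
  }
  invisible(path)
}
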