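test_that("the shipped co-culture product table reads into validated groups", {
  recs <- read_experiments(fixture_path("table2_experiments.csv"))
  # 11 of the 15 printed condition rows carry data ("no growth" rows do not)
  expect_equal(nrow(recs), 11)
  expect_equal(length(unique(recs$substrate)), 3)
  expect_equal(length(unique(recs$group)), 11)
  expect_true(all(is.na(recs$co2_mM))) # unmeasured, not zero
})

test_that("empty and malformed record files are handled per contract", {
  empty <- tempfile(fileext = ".csv")
  writeLines(paste(fermbalance:::.record_schema, collapse = ","), empty)
  recs <- read_experiments(empty)
  expect_s3_class(recs, "experiment_records")
  expect_equal(nrow(recs), 0)

  bad <- tempfile(fileext = ".csv")
  writeLines(c(
    paste(fermbalance:::.record_schema, collapse = ","),
    "x1,DIB004C,avicel,10,uncontrolled-flask,,-2.7,21.4,9.0,,,,1"
  ), bad)
  expect_error(read_experiments(bad), "row 1 \\(line 2\\).*negative")

  nocol <- tempfile(fileext = ".csv")
  writeLines("id,strains", nocol)
  expect_error(read_experiments(nocol), "missing column")

  badmode <- tempfile(fileext = ".csv")
  writeLines(c(
    paste(fermbalance:::.record_schema, collapse = ","),
    "x1,DIB004C,avicel,10,open-vat,,2.7,21.4,9.0,,,,1"
  ), badmode)
  expect_error(read_experiments(badmode), "ph_mode")
})

test_that("summaries aggregate per replicate and reproduce printed totals", {
  recs <- read_experiments(fixture_path("table2_experiments.csv"))
  s <- summarize_experiments(recs)
  co <- s[s$strains == "DIB004C+DIB097X" & s$substrate == "avicel", ]
  expect_equal(round_half_up(co$total_mean, 1), 40.7)
  expect_equal(co$ratio, "1 : 1.8 : 1.1")
  # single records report no spread
  expect_true(all(is.na(s$total_sd)))

  # replicated group: per-replicate statistics, then mean and sd
  reps <- validate_experiments(data.frame(
    id = c("a", "b", "c"), strains = "S", substrate = "glucose",
    loading_g_l = 10, ph_mode = "uncontrolled-flask",
    substrate_final_g_l = NA_real_,
    ethanol_mM = c(10, 12, 11), acetate_mM = c(5, 6, 4),
    lactate_mM = c(2, 2, 3), co2_mM = NA_real_, h2_mM = NA_real_,
    cdw_g_l = NA_real_, replicate = 1:3
  ))
  s2 <- summarize_experiments(reps)
  molpcts <- c(10 / 17, 12 / 20, 11 / 18) * 100
  expect_equal(s2$ethanol_molpct_mean, mean(molpcts))
  expect_equal(s2$ethanol_molpct_sd, sd(molpcts))
  # identical replicates have zero spread
  same <- reps
  same$ethanol_mM <- 10; same$acetate_mM <- 5; same$lactate_mM <- 2
  s3 <- summarize_experiments(validate_experiments(same))
  expect_equal(s3$total_sd, 0)
})

test_that("summaries are invariant to row order", {
  recs <- read_experiments(fixture_path("table2_experiments.csv"))
  shuffled <- validate_experiments(recs[rev(seq_len(nrow(recs))), ])
  a <- summarize_experiments(recs)
  b <- summarize_experiments(shuffled)
  key <- function(d) d[order(d$strains, d$substrate), , drop = FALSE]
  a <- key(a); b <- key(b)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("fermentation-balance rows recompute the published flask balances", {
  recs <- read_experiments(fixture_path("table3_experiments.csv"))
  b <- balance_experiments(recs)
  avicel <- b[b$strains == "DIB004C" & b$substrate == "avicel", ]
  expect_equal(round_half_up(avicel$consumed_equiv_mM, 1), 25.4)
  expect_equal(round_half_up(avicel$substrate_carbon_mM, 1), 152.5)
  # recomputed from printed column means; hand arithmetic gives the same
  expect_equal(round_half_up(avicel$carbon_recovery_pct, 1), 93.5)
  expect_equal(round_half_up(avicel$electron_recovery_pct, 1), 94.3)
  # the published replicate-mean recoveries (93.2 +/- 11.5, 103.0 +/- 10.3)
  # are not recomputable from the printed means; they agree within the
  # published replicate scatter
  expect_lt(abs(avicel$carbon_recovery_pct - 93.2), 11.5)
  expect_lt(abs(avicel$electron_recovery_pct - 103.0), 10.3)
  glc <- b[b$strains == "DIB004C" & b$substrate == "glucose", ]
  expect_equal(round_half_up(glc$consumed_equiv_mM, 1), 30.6)
  expect_lt(abs(glc$carbon_recovery_pct - 98.9), 3)
  expect_lt(abs(glc$electron_recovery_pct - 103.8), 3)
})

test_that("report writing round-trips CSV and renders markdown", {
  recs <- read_experiments(fixture_path("table2_experiments.csv"))
  s <- summarize_experiments(recs)
  out <- tempfile(fileext = ".csv")
  write_report(s, out, "csv")
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_equal(back$total_mean, s$total_mean)
  expect_equal(back$ratio, s$ratio)
  expect_equal(names(back), names(s)) # deterministic column order

  md <- tempfile(fileext = ".md")
  write_report(s, md, "markdown")
  lines <- readLines(md)
  expect_match(lines[1], "^\\| strains \\|")
  expect_equal(length(lines), nrow(s) + 2)

  expect_error(write_report(s[0, ], out), "non-empty")
})
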