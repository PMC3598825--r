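test_that("closure gases reproduce classic fermentation stoichiometries", {
  # glucose -> 2 acetate + 2 CO2 + 4 H2
  expect_equal(closure_gases(c(0, 2, 0)), c(co2 = 2, h2 = 4))
  # glucose -> 2 ethanol + 2 CO2 (redox-balanced, no H2)
  expect_equal(closure_gases(c(2, 0, 0)), c(co2 = 2, h2 = 0))
  # homolactic case is carbon- and redox-neutral
  expect_equal(closure_gases(c(0, 0, 2)), c(co2 = 0, h2 = 0))
  # pentose analog: 5 C, 20 electrons, 5/3 C3 units
  expect_equal(closure_gases(c(0, 5 / 3, 0), sugar = "pentose"),
               c(co2 = 5 / 3, h2 = 10 / 3))
})

test_that("closure gases reject infeasible splits", {
  # more organic carbon than the sugar carries
  expect_error(closure_gases(c(2, 0, 1)), "exceed substrate carbon")
  # electron deficit: all-ethanol plus biomass demands electrons
  # the substrate does not have
  expect_error(closure_gases(c(2 * 0.95, 0, 0) , biomass_c = 6 * 0.05),
               "electron deficit")
})

test_that("closure gases balance carbon and electrons for arbitrary feasible splits", {
  set.seed(7)
  for (i in 1:50) {
    w <- runif(3); w <- w / sum(w)
    f <- runif(1, 0, 0.1)
    org <- 2 * (1 - f) * w
    gas <- tryCatch(closure_gases(org, 6 * f), error = function(e) NULL)
    if (is.null(gas)) next
    carbon <- 2 * org[1] + 2 * org[2] + 3 * org[3] + gas[["co2"]] + 6 * f
    electrons <- 12 * org[1] + 8 * org[2] + 12 * org[3] +
      2 * gas[["h2"]] + 4.25 * 6 * f
    expect_equal(carbon, 6, tolerance = 1e-12)
    expect_equal(electrons, 24, tolerance = 1e-12)
  }
})

test_that("noise-free generated records close both balances exactly", {
  rec <- generate_outcome(cellu_strain(), pure_cellulose, 10,
                          noise = noise_model(0, 5),
                          ph_mode = "ph-controlled-fermentor")
  tr <- attr(rec, "truth")
  prof <- product_profile(tr$products[["ethanol"]], tr$products[["acetate"]],
                          tr$products[["lactate"]], co2 = tr$co2,
                          h2 = tr$h2, cell_carbon = tr$cell_carbon)
  expect_equal(carbon_recovery(tr$consumed, prof)$recovery, 100,
               tolerance = 1e-12)
  expect_equal(electron_recovery(tr$consumed, prof)$recovery, 100,
               tolerance = 1e-12)
  # at zero noise the measured record equals the truth
  expect_equal(rec$ethanol_mM, tr$products[["ethanol"]])
  expect_equal(rec$co2_mM, tr$co2)
})

test_that("generated records are deterministic for a fixed seed", {
  args <- list(cellu_strain(), pure_cellulose, 10,
               noise = noise_model(0.05, 11))
  r1 <- do.call(generate_outcome, args)
  r2 <- do.call(generate_outcome, args)
  expect_identical(r1, r2)
  r3 <- do.call(generate_outcome, modifyList(args,
                                             list(noise = noise_model(0.05, 12))))
  expect_false(identical(r1$ethanol_mM, r3$ethanol_mM))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_outcome(cellu_strain(), pure_cellulose, 10,
                             noise = noise_model(0.05, 11)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("co-cultures with an ethanologenic partner raise ethanol severalfold", {
  mono <- generate_outcome(cellu_strain(), pure_cellulose, 10,
                           noise = noise_model(0, 21))
  co <- generate_outcome(list(cellu_strain(), thermo_strain()),
                         pure_cellulose, 10, noise = noise_model(0, 21))
  fc <- co$ethanol_mM / mono$ethanol_mM
  expect_gt(fc, 2)
})

test_that("saccharolytic strains cannot grow alone on polymeric substrates", {
  expect_error(
    generate_outcome(thermo_strain(), pure_cellulose, 10),
    "hydrolyze"
  )
  # but do ferment defined sugars
  rec <- generate_outcome(thermo_strain(), sugars(glucose = 55.51),
                          noise = noise_model(0, 2),
                          ph_mode = "ph-controlled-fermentor")
  expect_gt(rec$ethanol_mM, 0)
  expect_equal(rec$substrate, "glucose")
})

test_that("carbon is conserved in every generated record before noise", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_strain()
    rec <- generate_outcome(s, pure_cellulose, runif(1, 2, 20),
                            noise = noise_model(0, i),
                            ph_mode = "ph-controlled-fermentor")
    tr <- attr(rec, "truth")
    substrate_c <- 6 * sum(unclass(tr$consumed)[c("glucose", "galactose",
                                                  "mannose")]) +
      5 * sum(unclass(tr$consumed)[c("xylose", "arabinose")])
    product_c <- 2 * tr$products[["ethanol"]] + 2 * tr$products[["acetate"]] +
      3 * tr$products[["lactate"]] + tr$co2 + tr$cell_carbon
    expect_equal(product_c, substrate_c, tolerance = 1e-9)
  }
})

test_that("flask acidification caps totals below the fermentor outcome", {
  flask <- generate_outcome(cellu_strain(), pure_cellulose, 10,
                            noise = noise_model(0, 4),
                            ph_mode = "uncontrolled-flask",
                            acid_threshold = 30)
  ferm <- generate_outcome(cellu_strain(), pure_cellulose, 10,
                           noise = noise_model(0, 4),
                           ph_mode = "ph-controlled-fermentor")
  tf <- flask$ethanol_mM + flask$acetate_mM + flask$lactate_mM
  tt <- ferm$ethanol_mM + ferm$acetate_mM + ferm$lactate_mM
  expect_lt(tf, tt)
  expect_equal(flask$acetate_mM + flask$lactate_mM, 30, tolerance = 1e-9)
  # the capped record still closes both balances exactly
  tr <- attr(flask, "truth")
  prof <- product_profile(tr$products[["ethanol"]], tr$products[["acetate"]],
                          tr$products[["lactate"]], co2 = tr$co2,
                          h2 = tr$h2, cell_carbon = tr$cell_carbon)
  expect_equal(carbon_recovery(tr$consumed, prof)$recovery, 100,
               tolerance = 1e-12)
})

test_that("time courses start at zero, rise monotonically and hit the end point", {
  tc <- generate_timecourse(cellu_strain(), pure_cellulose, 10,
                            n_points = 9, noise = noise_model(0, 6),
                            ph_mode = "ph-controlled-fermentor")
  expect_equal(tc$ethanol_mM[1], 0)
  expect_equal(tc$acetate_mM[1], 0)
  expect_true(all(diff(tc$ethanol_mM) >= 0))
  expect_true(all(diff(tc$lactate_mM) >= 0))
  expect_true(all(diff(tc$substrate_g_l) <= 0))
  ep <- attr(tc, "endpoint")
  expect_equal(tc$ethanol_mM[nrow(tc)], ep$ethanol_mM)
  expect_equal(tc$substrate_g_l[nrow(tc)], ep$substrate_final_g_l)
  expect_true(all(diff(tc$time_h) > 0))
  expect_error(generate_timecourse(cellu_strain(), pure_cellulose, 10,
                                   n_points = 1), "at least 2")
})

test_that("flask time courses plateau below the fermentor end point", {
  flask <- generate_timecourse(cellu_strain(), pure_cellulose, 10,
                               n_points = 13, noise = noise_model(0, 6),
                               ph_mode = "uncontrolled-flask",
                               acid_threshold = 15)
  ferm <- generate_timecourse(cellu_strain(), pure_cellulose, 10,
                              n_points = 13, noise = noise_model(0, 6),
                              ph_mode = "ph-controlled-fermentor")
  n <- nrow(flask)
  expect_lt(flask$ethanol_mM[n] + flask$acetate_mM[n] + flask$lactate_mM[n],
            ferm$ethanol_mM[n] + ferm$acetate_mM[n] + ferm$lactate_mM[n])
})

test_that("product splits are recovered from generated records", {
  truth <- c(0.25, 0.5, 0.25)
  s <- strain_params("s", truth, biomass_fraction = 0,
                     consumption_extent = 0.8, scope = "cellulolytic")
  clean <- generate_outcome(s, pure_cellulose, 10, noise = noise_model(0, 8),
                            ph_mode = "ph-controlled-fermentor")
  expect_equal(unname(estimate_split(clean)), truth, tolerance = 1e-12)

  # ethanol-only record
  eth <- strain_params("e", c(1, 0, 0), biomass_fraction = 0,
                       scope = "cellulolytic")
  rec <- generate_outcome(eth, pure_cellulose, 10, noise = noise_model(0, 9),
                          ph_mode = "ph-controlled-fermentor")
  expect_equal(unname(estimate_split(rec)), c(1, 0, 0))

  # mean over 200 noisy replicates is within 0.02 of the truth
  ests <- sapply(1:200, function(r) {
    rec <- generate_outcome(s, pure_cellulose, 10,
                            noise = noise_model(0.05, 1000 + r),
                            ph_mode = "ph-controlled-fermentor")
    estimate_split(rec)
  })
  expect_true(all(abs(rowMeans(ests) - truth) < 0.02))

  expect_error(estimate_split(product_profile(0, 0, 0)), "no organic products")
})

test_that("strain parameter validation enforces the stated ranges", {
  expect_error(strain_params("x", c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(strain_params("x", c(-0.1, 0.6, 0.5)), "summing to 1|non-negative")
  expect_error(strain_params("x", c(0.3, 0.4, 0.3), biomass_fraction = 0.3),
               "0.15")
  expect_error(strain_params("x", c(0.3, 0.4, 0.3), consumption_extent = 1.2),
               "\\[0, 1\\]")
  expect_error(noise_model(-0.1), "non-negative")
})
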