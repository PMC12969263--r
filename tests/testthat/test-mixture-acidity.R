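# Acidity scales and ion partitioning in H2O/D2O mixtures.

test_that("pure-water ionic product matches the empirical fit and decreases with T", {
  # frozen from a high-precision independent evaluation of the fit
  expect_equal(pkw_water(298.15), 13.9996513961490, tolerance = 1e-12)
  expect_equal(pkw_water(293.15), 14.1681270511755, tolerance = 1e-12)
  grid <- seq(278, 323, by = 0.5)
  expect_true(all(diff(pkw_water(grid)) < 0))
  expect_error(pkw_water(-5), class = "hdxmix_domain_error")
})

test_that("mixture ionic-product shift follows the cubic on [0,1]", {
  expect_identical(delta_pkw(0), 0)
  expect_equal(delta_pkw(1), 0.8620, tolerance = 1e-12)
  expect_equal(delta_pkw(0.5), 0.387225, tolerance = 1e-12)
  expect_error(delta_pkw(1.2), class = "hdxmix_domain_error")
  expect_error(delta_pkw(-0.1), class = "hdxmix_domain_error")
})

test_that("glass-electrode conversion recovers the classic pD correction", {
  expect_equal(pl_from_ph_read(7, x = 1), 7.43, tolerance = 5e-3)
  expect_equal(pl_from_ph_read(7, x = 1), 7.43101073228579, tolerance = 1e-12)
  expect_equal(pl_from_ph_read(7, x = 0.5), 7.19361732112455, tolerance = 1e-12)
  # pure H2O: the reading is the acidity
  expect_identical(pl_from_ph_read(5.3, x = 0), 5.3)
})

test_that("solvent_condition validates its domain and acidity specification", {
  expect_error(solvent_condition(x = 1.5, ph_read = 7),
               class = "hdxmix_domain_error")
  expect_error(solvent_condition(x = 0.5, temperature = -1, ph_read = 7),
               class = "hdxmix_domain_error")
  expect_error(solvent_condition(x = 0.5), class = "hdxmix_config_error")
  expect_error(solvent_condition(x = 0.5, ph_read = 7, pl = 7),
               class = "hdxmix_config_error")
  expect_warning(solvent_condition(x = 0, temperature = 380, ph_read = 7),
                 "outside")
  expect_warning(solvent_condition(x = 0.5, temperature = 278.15, ph_read = 7),
                 "298")
})

test_that("ion_state satisfies pL + pOL = pKw and conserves lyoxide", {
  set.seed(11)
  for (i in 1:25) {
    x <- runif(1)
    mode <- sample(c("ph_read", "pl", "pol"), 1)
    args <- list(x = x, temperature = runif(1, 283.15, 313.15))
    args[[mode]] <- runif(1, 5, 9)
    st <- ion_state(quiet_condition(
      x = args$x, temperature = args$temperature,
      ph_read = args$ph_read, pl = args$pl, pol = args$pol))
    expect_equal(st$pL + st$pOL, st$pKw_mix, tolerance = 1e-12)
    expect_identical(st$conc_OH + st$conc_OD, st$conc_OL)
    expect_true(all(c(st$conc_OH, st$conc_OD, st$conc_OL) >= 0))
  }
})

test_that("ion partition respects the pure-solvent limits", {
  h2o <- ion_state(solvent_condition(x = 0, ph_read = 7))
  expect_identical(h2o$conc_OD, 0)
  expect_equal(h2o$pOL, pkw_water(298.15) - 7, tolerance = 1e-12)
  d2o <- ion_state(solvent_condition(x = 1, ph_read = 7))
  expect_identical(d2o$conc_OH, 0)
  expect_equal(d2o$pL, 7.431, tolerance = 1e-3)
  # near-neutral D2O: pL close to pOL
  expect_equal(d2o$pL, d2o$pOL, tolerance = 0.01)
})

test_that("resolution is idempotent across acidity scales", {
  base <- ion_state(solvent_condition(x = 0.7, ph_read = 6.5))
  via_pl <- ion_state(solvent_condition(x = 0.7, pl = base$pL))
  via_pol <- ion_state(solvent_condition(x = 0.7, pol = base$pOL))
  expect_equal(via_pl$conc_OH, base$conc_OH, tolerance = 1e-14)
  expect_equal(via_pl$conc_OD, base$conc_OD, tolerance = 1e-14)
  expect_equal(via_pol$conc_OL, base$conc_OL, tolerance = 1e-14)
})

test_that("at fixed pH* both pL and pOL rise with D2O content", {
  xs <- seq(0, 1, by = 0.1)
  states <- lapply(xs, function(x) ion_state(solvent_condition(x, ph_read = 7)))
  expect_true(all(diff(vapply(states, `[[`, numeric(1), "pL")) > 0))
  expect_true(all(diff(vapply(states, `[[`, numeric(1), "pOL")) > 0))
})
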