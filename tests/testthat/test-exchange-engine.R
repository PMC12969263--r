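# Forward/back rates, weighting, equilibrium, kinetics, protection.

test_that("tilde rates recover single-channel limits in pure solvents", {
  rr <- reference_rates("PDLA")
  h2o <- ion_state(solvent_condition(x = 0, ph_read = 7))
  tk0 <- tilde_rates(h2o, rr)
  k0 <- hdxmix:::scaled_linear_rates(rr, 298.15)
  expect_equal(tk0$tilde_forward, k0$kHH * h2o$conc_OH, tolerance = 1e-12)
  expect_equal(tk0$tilde_backward, k0$kDH * h2o$conc_OH, tolerance = 1e-12)
  d2o <- ion_state(solvent_condition(x = 1, ph_read = 7))
  tk1 <- tilde_rates(d2o, rr)
  expect_equal(tk1$tilde_forward, k0$kHD * d2o$conc_OD, tolerance = 1e-12)
  expect_equal(tk1$tilde_backward, k0$kDD * d2o$conc_OD, tolerance = 1e-12)
})

test_that("forward/back ratio equals kHH/kDH across composition, acidity and T", {
  rr <- reference_rates("PDLA")
  phi <- 10^(rr$log_kHH - rr$log_kDH)
  for (x in seq(0.05, 0.95, length.out = 10)) {
    for (ph in seq(5, 9, length.out = 5)) {
      for (temp in seq(278.15, 323.15, length.out = 5)) {
        st <- ion_state(quiet_condition(x = x, temperature = temp,
                                        ph_read = ph))
        tk <- tilde_rates(st, rr)
        expect_equal(tk$tilde_forward / tk$tilde_backward, phi,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("insertion weighting is linear in x and kills the right endpoint", {
  w0 <- weighted_rates(0, 3, 5)
  expect_identical(w0$k_forward, 0)
  expect_identical(w0$k_backward, 5)
  w1 <- weighted_rates(1, 3, 5)
  expect_identical(w1$k_forward, 3)
  expect_identical(w1$k_backward, 0)
  wh <- weighted_rates(0.5, 3, 5)
  expect_identical(wh$k_forward, 1.5)
  expect_identical(wh$k_backward, 2.5)
  expect_error(weighted_rates(1.1, 1, 1), class = "hdxmix_domain_error")
})

test_that("equilibrium deuteration follows the closed form and its limits", {
  rr <- reference_rates("PDLA")
  phi <- base_catalyzed_phi(rr)
  for (x in seq(0.1, 0.9, by = 0.1)) {
    st <- ion_state(solvent_condition(x = x, ph_read = 7))
    tk <- tilde_rates(st, rr)
    wk <- weighted_rates(x, tk$tilde_forward, tk$tilde_backward)
    deq <- equilibrium_deuteration(wk$k_forward, wk$k_backward)
    expect_equal(deq, deq_closed_form(x, phi), tolerance = 1e-12)
    expect_gt(deq, x)  # amide enriched relative to solvent
  }
  expect_equal(equilibrium_deuteration(0, 2), 0)
  expect_equal(equilibrium_deuteration(2, 0), 1)
  expect_error(equilibrium_deuteration(0, 0), class = "hdxmix_domain_error")
  # x = 0.5 PDLA: phi/(1+phi)
  st <- ion_state(solvent_condition(x = 0.5, ph_read = 7))
  tk <- tilde_rates(st, rr)
  wk <- weighted_rates(0.5, tk$tilde_forward, tk$tilde_backward)
  expect_equal(equilibrium_deuteration(wk$k_forward, wk$k_backward),
               phi / (1 + phi), tolerance = 1e-12)
  expect_equal(phi / (1 + phi), 0.546, tolerance = 1e-3)
})

test_that("uptake curve satisfies initial condition, plateau, half-life and ODE", {
  d0 <- 0.05; deq <- 0.87; k <- 3.2
  times <- c(0, 10^seq(-3, 1, length.out = 40), log(2) / k)
  uc <- uptake_curve(d0, deq, k, times)
  expect_equal(uc$d[uc$time == 0], d0, tolerance = 1e-12)
  expect_equal(uptake_curve(d0, deq, k, 1e4)$d, deq, tolerance = 1e-12)
  expect_equal(uc$d[uc$time == log(2) / k], (d0 + deq) / 2, tolerance = 1e-12)
  expect_true(all(uc$d >= 0 & uc$d <= 1))
  expect_true(all(diff(uc$d) >= 0))  # monotone toward d_eq from below
  # two-state ODE: dD/dt = k_forw - k_int * D, with k_forw = d_eq * k_int
  h <- 1e-6
  for (t in c(0.01, 0.1, 0.5, 1)) {
    num <- (uptake_curve(d0, deq, k, t + h)$d -
              uptake_curve(d0, deq, k, t - h)$d) / (2 * h)
    d_t <- uptake_curve(d0, deq, k, t)$d
    expect_equal(num, deq * k - k * d_t, tolerance = 1e-5)
  }
  expect_error(uptake_curve(d0, deq, k, -1), class = "hdxmix_domain_error")
  expect_error(uptake_curve(-0.2, deq, k, 1), class = "hdxmix_domain_error")
})

test_that("protection attenuates the observed rate", {
  expect_identical(observed_rate(4, 0), 4)
  expect_identical(observed_rate(4, 1), 2)
  ps <- 10^seq(0, 6, by = 1)
  expect_true(all(diff(observed_rate(4, ps)) < 0))
  expect_lt(observed_rate(4, 1e9), 1e-8)
  expect_error(observed_rate(4, -0.1), class = "hdxmix_domain_error")
})

test_that("residue profile aligns with sequence positions and flags gaps", {
  cond <- solvent_condition(x = 0.9, ph_read = 7)
  ala <- residue_profile("AAAAAAA", cond)
  expect_identical(nrow(ala), 7L)
  expect_false(ala$exchanging[1])
  inner <- ala$k_int[3:6]  # interior residues share identical neighbours
  expect_true(all(abs(inner - inner[1]) < 1e-12 * inner[1]))
  pep <- residue_profile("PEPTIDE", cond)
  expect_identical(pep$flag[pep$residue == "P"], c("n-terminal", "proline"))
  expect_true(all(is.na(pep$k_int[!pep$exchanging])))
  expect_true(all(pep$k_int[pep$exchanging] > 0))
  expect_error(residue_profile("", cond), class = "hdxmix_input_error")
})

test_that("dipeptide in pure D2O matches the hand-computed single-channel rate", {
  # k_HD scaled 20->25 degC, times 10^(1.62 - 1.80) terminal factors,
  # times [OD-] at pH* = 7; frozen from an independent high-precision
  # evaluation
  prof <- residue_profile("AA", solvent_condition(x = 1, ph_read = 7))
  expect_equal(prof$k_forward[2], 605.197402368868, tolerance = 1e-9)
  expect_identical(prof$k_backward[2], 0)
})

test_that("acid/water extension reduces to base-only and adds at both endpoints", {
  rr <- reference_rates("PDLA")
  st <- ion_state(solvent_condition(x = 0.5, ph_read = 7))
  base_only <- tilde_rates(st, rr)
  expect_identical(extended_rates(st, rr), base_only)
  water <- reference_rate_set(-4, -4.2, -3.9, t_ref = 293.15)
  for (x in c(0, 0.5, 1)) {
    s <- ion_state(solvent_condition(x = x, ph_read = 7))
    ext <- extended_rates(s, rr, refset_water = water)
    b <- tilde_rates(s, rr)
    expect_gt(ext$tilde_forward, b$tilde_forward)
    expect_gt(ext$tilde_backward, b$tilde_backward)
  }
  expect_error(extended_rates(st, rr, refset_acid = list(a = 1)),
               class = "hdxmix_config_error")
})
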