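# thermodynamic-relaxation SSME simulator: stoichiometry, drives, invariances

test_that("net charge per cycle follows the stoichiometry", {
  expect_equal(net_charge_per_cycle(transporter_params("antiport",
                                                       n_H = 2, n_D = 1,
                                                       z_D = 1)), 1)
  expect_equal(net_charge_per_cycle(transporter_params("symport",
                                                       n_H = 1, n_D = 1,
                                                       z_D = 1)), 2)
  expect_equal(net_charge_per_cycle(transporter_params("drug_uniport",
                                                       z_D = 1)), 1)
  expect_equal(net_charge_per_cycle(transporter_params("proton_uniport",
                                                       n_H = 1, z_D = 0)), 1)
  expect_equal(net_charge_per_cycle(transporter_params("inactive")), 0)
})

test_that("gradient arithmetic: 16-fold drug and ~2-fold proton gradients", {
  conds <- standard_gradient_conditions()
  folds <- gradient_folds(conds$with_proton_gradient)
  expect_equal(folds$drug_fold, 16)
  expect_equal(folds$proton_fold, 10^0.3)
  expect_equal(round(folds$proton_fold), 2)
})

test_that("antiport charge flips sign when the drug gradient is inverted", {
  p <- transporter_params("antiport")
  conds <- standard_gradient_conditions()
  q_with <- steady_state_charge(p, conds$with_proton_gradient)
  q_against <- steady_state_charge(p, conds$against_proton_gradient)
  q_nog <- steady_state_charge(p, conds$no_gradient)
  expect_lt(q_with, 0)
  expect_gt(q_against, 0)
  expect_gt(q_nog, 0)
  expect_gt(q_against, q_nog)  # aligned drive enhances the signal
  # swapping drug_in/drug_out negates the drug term exactly
  swapped <- gradient_condition("with_proton_gradient", drug_in = 8,
                                drug_out = 0.5)
  d1 <- steady_state_charge(p, conds$with_proton_gradient) - q_nog
  d2 <- steady_state_charge(p, swapped) - q_nog
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("proton-uniport charge is invariant to the drug gradient", {
  p <- transporter_params("proton_uniport", z_D = 0, Km_gate = 5)
  qs <- vapply(list(c(8, 8), c(0.5, 8), c(8, 0.5), c(2, 8)), function(d) {
    cond <- gradient_condition("no_gradient", drug_in = d[1], drug_out = d[2])
    steady_state_charge(p, cond)
  }, 0)
  # same max-side concentration -> exactly equal at zero noise
  expect_equal(qs, rep(qs[1], 4))
  expect_gt(qs[1], 0)
  # gating saturates with Km_gate: charge grows with drug toward a plateau
  q_of <- function(conc) steady_state_charge(
    p, gradient_condition("no_gradient", drug_in = conc, drug_out = conc))
  expect_lt(q_of(0.5), q_of(5))
  expect_equal(q_of(5) - p$leak0 * log(10^0.3),
               (q_of(5000) - p$leak0 * log(10^0.3)) * 0.5 / (1 - 5 / 5005),
               tolerance = 0.01)
})

test_that("a neutral uniported drug moves no charge under any gradient", {
  p <- transporter_params("drug_uniport", z_D = 0, leak0 = 0)
  for (cond in standard_gradient_conditions()) {
    expect_equal(steady_state_charge(p, cond), 0)
    tr <- simulate_ssme_trace(p, cond, noise_sd = 0, offset_nA = 0, seed = 1)
    expect_equal(max(abs(tr$current)), 0)
  }
})

test_that("coupled modes are silent without drug; inactive shows only leak", {
  nd <- standard_gradient_conditions()$no_drug
  leak <- 0.02 * log(10^0.3)
  for (mode in c("antiport", "symport", "proton_uniport")) {
    p <- transporter_params(mode, z_D = if (mode == "proton_uniport") 0 else 1)
    expect_equal(steady_state_charge(p, nd), leak, tolerance = 1e-12)
  }
  p_in <- transporter_params("inactive")
  for (cond in standard_gradient_conditions()) {
    expect_equal(steady_state_charge(p_in, cond), leak, tolerance = 1e-12)
  }
})

test_that("simulated traces have three contiguous phases and the planted Q", {
  p <- transporter_params("antiport")
  cond <- standard_gradient_conditions()$against_proton_gradient
  tr <- simulate_ssme_trace(p, cond, noise_sd = 0, seed = 1)
  expect_identical(tr$phases$phase, c("internal_1", "external", "internal_2"))
  expect_equal(tr$phases$t_start[-1], tr$phases$t_end[-3])
  expect_equal(integrate_trace(tr)$total_charge,
               steady_state_charge(p, cond), tolerance = 0.01)
  expect_error(simulate_ssme_trace(p, cond, duration = 1, dt = 2),
               class = "ms_invalid_sampling")
})

test_that("traces and experiments are seed-deterministic", {
  p <- transporter_params("proton_uniport", z_D = 0)
  cond <- standard_gradient_conditions()$no_gradient
  a <- simulate_ssme_trace(p, cond, seed = 77)
  b <- simulate_ssme_trace(p, cond, seed = 77)
  expect_identical(a, b)
  e1 <- simulate_ssme_experiment(p, seed = 8, n_sensors = 2)
  e2 <- simulate_ssme_experiment(p, seed = 8, n_sensors = 2)
  expect_identical(measure_charges(e1), measure_charges(e2))
})
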