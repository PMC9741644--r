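# SSME trace analysis: integration, gating kinetics, mode classification, QC

test_that("integrate_trace subtracts the 100-ms baseline and integrates", {
  # identically zero current
  z <- make_const_trace(i_internal = 0, i_external = 0)
  expect_equal(integrate_trace(z)$total_charge, 0)
  # baseline 0.5 nA, external 1.0 s at 2.0 nA -> 1.5 nC
  tr <- make_const_trace(i_internal = 0.5, i_external = 2.0, t_ext = 1.0)
  m <- integrate_trace(tr)
  expect_equal(m$baseline_current, 0.5)
  expect_equal(m$total_charge, 1.5)
  # exponential transient recovers Q_ss within 1% for a window >= 5 tau
  tau <- 0.2
  q_ss <- 3.7
  tr2 <- make_const_trace(i_internal = 0, t_ext = 5 * tau, dt = 0.002)
  ext <- tr2$time >= 0.5 & tr2$time <= 0.5 + 5 * tau
  tr2$current[ext] <- (q_ss / tau) * exp(-(tr2$time[ext] - 0.5) / tau)
  expect_equal(integrate_trace(tr2)$total_charge, q_ss, tolerance = 0.01)
})

test_that("integration is linear and guards its phase windows", {
  tr <- simulate_ssme_trace(transporter_params("antiport"),
                            standard_gradient_conditions()$no_gradient,
                            seed = 3)
  q1 <- integrate_trace(tr)$total_charge
  tr3 <- tr
  tr3$current <- 3 * tr$current
  expect_equal(integrate_trace(tr3)$total_charge, 3 * q1)
  short <- tr
  short$phases$t_end[1] <- 0.05
  expect_error(integrate_trace(short), class = "ms_baseline_window_error")
  nophase <- tr
  nophase$phases <- tr$phases[-2, ]
  expect_error(integrate_trace(nophase), class = "ms_phase_error")
})

test_that("fit_gating recovers Michaelis-Menten parameters", {
  conc <- c(0.5, 1, 2, 5, 10, 20, 50)
  # closed form: half-maximal response at c = Km
  expect_equal(1 * 5 / (5 + 5), 0.5)
  fit <- fit_gating(conc, 1 * conc / (5 + conc))
  expect_equal(fit$Km, 5, tolerance = 1e-6)
  expect_equal(fit$Imax, 1, tolerance = 1e-6)
  expect_error(fit_gating(c(1, 2), c(0.1, 0.2)), class = "ms_invalid_grid")
  # sub-saturating grid (max conc << Km) warns
  cc <- c(5, 10, 20, 40)
  expect_warning(fit_gating(cc, cc / (100 + cc)),
                 class = "ms_ill_conditioned")
  # strictly linear response cannot constrain Km at all
  expect_error(fit_gating(c(1, 2, 4, 8), c(1, 2, 4, 8) * 1e-3),
               class = "ms_fit_failure")
})

test_that("Km rescales with the concentration axis (equivariance)", {
  conc <- c(0.5, 1, 2, 5, 10, 20, 50)
  resp <- 2 * conc / (5 + conc)
  f1 <- fit_gating(conc, resp)
  f2 <- fit_gating(conc * 7, resp)
  expect_equal(f2$Km, 7 * f1$Km, tolerance = 1e-6)
})

test_that("packaged gating preset recovers Km within the printed range", {
  gd <- generate_preset("harmane_gating")
  fit <- fit_gating(gd$conc_uM, gd$peak_nA)
  expect_lt(abs(fit$Km - 5), 1)
})

test_that("classifier reproduces the expected pattern for each mode", {
  run_mode <- function(params, seed = 11) {
    ch <- measure_charges(simulate_ssme_experiment(params, seed = seed))
    classify_mode(ch, drug_charge = params$z_D)
  }
  expect_identical(run_mode(transporter_params("antiport"))$mode, "antiport")
  expect_identical(run_mode(transporter_params("symport", n_H = 1))$mode,
                   "symport")
  expect_identical(run_mode(transporter_params("drug_uniport", z_D = 1))$mode,
                   "drug_uniport")
  expect_identical(
    run_mode(transporter_params("proton_uniport", z_D = 0))$mode,
    "proton_uniport")
  expect_identical(run_mode(transporter_params("inactive"))$mode, "inactive")
  # neutral uniported substrate is electrically silent -> inactive
  expect_identical(
    run_mode(transporter_params("drug_uniport", z_D = 0))$mode, "inactive")
})

test_that("classifier requires all four conditions", {
  ch <- measure_charges(simulate_ssme_experiment(
    transporter_params("antiport"), seed = 2))
  expect_error(classify_mode(ch[ch$condition != "no_drug", ]),
               class = "ms_input_error")
})

test_that("very low SNR degrades to inactive/ambiguous, never a wrong mode", {
  wrong <- 0L
  for (seed in 1:20) {
    ch <- measure_charges(simulate_ssme_experiment(
      transporter_params("antiport"), seed = seed, noise_sd = 50))
    call <- classify_mode(ch)$mode
    if (!call %in% c("inactive", "ambiguous")) wrong <- wrong + 1L
  }
  expect_lte(wrong / 20, 0.05)
})

test_that("negating traces never preserves a coupled-transport call", {
  exp_a <- simulate_ssme_experiment(transporter_params("antiport"), seed = 5)
  ch <- measure_charges(exp_a)
  expect_identical(classify_mode(ch)$mode, "antiport")
  neg <- ch
  neg$total_charge <- -neg$total_charge
  flipped <- classify_mode(neg)$mode
  expect_false(flipped %in% c("antiport", "drug_uniport", "proton_uniport"))
})

test_that("sensor_qc enforces the capacitance band and strict conductance", {
  expect_true(sensor_qc(20, 1.5))
  expect_false(sensor_qc(35, 5))   # conductance bound is strict
  expect_false(sensor_qc(10, 1))
  expect_true(sensor_qc(15, 4.9))
  expect_identical(sensor_qc(c(20, 36), c(1, 1)), c(TRUE, FALSE))
})
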