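# dose-response fitting, MIC rule, FIC synergy analysis

test_that("relative growth normalises per replicate to the zero-drug OD", {
  plate <- data.frame(conc_uM = rep(c(0, 10), 2),
                      od600 = c(0.50, 0.25, 0.40, 0.30),
                      replicate = c(1, 1, 2, 2))
  dr <- relative_growth(plate)
  expect_equal(dr$relative_growth, c(1, 0.5, 1, 0.75))
  bad <- data.frame(conc_uM = c(0, 10), od600 = c(0, 0))
  expect_error(relative_growth(bad), class = "ms_normalization_error")
  nozero <- data.frame(conc_uM = c(5, 10), od600 = c(1, 1))
  expect_error(relative_growth(nozero), class = "ms_normalization_error")
})

test_that("fit_ic50 recovers noiseless sigmoids exactly", {
  conc <- c(0, 10, 30, 60, 130, 260, 520, 1000)
  g <- 1 / (1 + (conc / 130)^2)
  expect_equal(g[conc == 130], 0.5)  # closed form at c = ic50
  fit <- fit_ic50(data.frame(conc_uM = conc, relative_growth = g))
  expect_equal(fit$ic50, 130, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  flat <- data.frame(conc_uM = conc, relative_growth = rep(1, 8))
  expect_error(fit_ic50(flat), class = "ms_fit_failure")
})

test_that("compare_strains reports the fractional IC50 reduction", {
  f <- function(ic50, se = 0.001) structure(list(ic50 = ic50, se_ic50 = se),
                                            class = "ms_ic50_fit")
  cmp <- compare_strains(f(0.078), f(0.13))
  expect_equal(cmp$percent_lower, 40)
  expect_false(cmp$no_difference)
  same <- compare_strains(f(0.1), f(0.1))
  expect_equal(same$percent_lower, 0)
  expect_true(same$no_difference)
})

test_that("MIC uses the sustained 10%-growth rule and censors cleanly", {
  conc <- c(0, 1, 2, 4, 8)
  expect_equal(compute_mic(conc, c(1.0, 0.8, 0.4, 0.08, 0.01))$mic, 4)
  # dip-then-regrowth: inhibition must be sustained
  expect_equal(compute_mic(conc, c(1.0, 0.05, 0.5, 0.05, 0.02))$mic, 4)
  cens <- compute_mic(conc, c(1.0, 0.9, 0.8, 0.7, 0.6))
  expect_true(cens$censored)
  expect_true(is.na(cens$mic))
  expect_equal(cens$limit, 8)
  # pointwise-lower growth can only lower (or keep) the MIC
  g <- c(1.0, 0.8, 0.4, 0.08, 0.01)
  expect_lte(compute_mic(conc, g * 0.5)$mic, compute_mic(conc, g)$mic)
})

test_that("fic_index implements the MIC-ratio arithmetic and boundaries", {
  f <- fic_index(8, 4, 1, 1)     # MIC_A/8 and MIC_B/4
  expect_equal(f$fic, 0.375)
  expect_identical(f$call, "synergistic")
  f2 <- fic_index(8, 4, 8, 4)    # combination leaves both MICs unchanged
  expect_equal(f2$fic, 2)
  expect_identical(f2$call, "antagonistic")
  expect_identical(fic_index(1, 1, 0.25, 0.24)$call, "synergistic")
  # FIC exactly 0.5 is indifferent (boundary inclusive), 1.0 antagonistic
  expect_equal(fic_index(1, 1, 0.25, 0.25)$fic, 0.5)
  expect_identical(fic_index(1, 1, 0.25, 0.25)$call, "indifferent")
  expect_identical(fic_index(1, 1, 0.5, 0.499)$call, "indifferent")
  expect_identical(fic_index(1, 1, 0.5, 0.5)$call, "antagonistic")
})

test_that("compute_fic recovers the packaged checkerboard calibrations", {
  syn <- compute_fic(generate_preset("kanamycin_harmane"))
  expect_identical(syn$call, "synergistic")
  expect_lt(abs(syn$fic - 0.375), 0.0375)
  ind <- compute_fic(generate_preset("tetracycline_harmane"))
  expect_identical(ind$call, "indifferent")
  expect_lt(abs(ind$fic - 0.58), 0.05)
  # conservation: fic = fic_a + fic_b for every interface well
  w <- syn$interface_wells
  expect_equal(w$fic, w$fic_a + w$fic_b)
})

test_that("FIC is invariant to rescaling the concentration axes", {
  cb <- generate_preset("kanamycin_harmane")
  scaled <- cb
  scaled$gridA <- cb$gridA * 1000
  scaled$gridB <- cb$gridB / 7
  f1 <- compute_fic(cb)
  f2 <- compute_fic(scaled)
  expect_equal(f2$fic, f1$fic)
  expect_identical(f2$call, f1$call)
})

test_that("planted interactions are recovered across seeds (round-trip)", {
  gridA <- c(0, 0.625, 1.25, 2.5, 5, 10, 20, 40, 80)
  gridB <- c(0, 9, 18, 36, 72, 144, 287.5, 575, 1150)
  calls <- sapply(1:100, function(seed) {
    syn <- compute_fic(gen_checkerboard(gridA, gridB, mic_a = 20, mic_b = 500,
                                        interaction = "synergy", seed = seed))
    ind <- compute_fic(gen_checkerboard(gridA, gridB, mic_a = 5.6 * 5,
                                        mic_b = 575,
                                        interaction = "indifferent",
                                        seed = seed))
    ant <- compute_fic(gen_checkerboard(gridA, gridB, mic_a = 20, mic_b = 500,
                                        interaction = "antagonist",
                                        seed = seed))
    c(syn$call == "synergistic", ind$call == "indifferent",
      ant$call == "antagonistic")
  })
  expect_gte(mean(calls[1, ]), 0.95)
  expect_gte(mean(calls[2, ]), 0.95)
  expect_gte(mean(calls[3, ]), 0.95)
})

test_that("checkerboards without a zero row/column or censored MICs error", {
  expect_error(gen_checkerboard(c(1, 2, 4), c(0, 1, 2)),
               class = "ms_invalid_design")
  cb <- generate_preset("kanamycin_harmane")
  weak <- cb
  weak$od[, 1] <- cb$od[1, 1]  # drug A never inhibits alone
  expect_error(compute_fic(weak), class = "ms_cannot_normalize")
})
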