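# differential phenotype-screen scoring

test_that("curve_auc is a baseline-subtracted trapezoid", {
  # flat curve integrates to zero regardless of offset
  expect_equal(curve_auc(0:10, rep(7.3, 11)), 0)
  # hand trapezoid: (0,0) (1,2) (2,2) -> 1 + 2 = 3
  expect_equal(curve_auc(c(0, 1, 2), c(0, 2, 2)), 3.0)
  # linear ramp 0 -> 10 over 24 h: triangle area 120
  expect_equal(curve_auc(seq(0, 24, by = 0.25), seq(0, 10, length.out = 97)),
               120)
  # offset invariance
  tt <- seq(0, 24, length.out = 50)
  y <- cumsum(runif(50))
  expect_equal(curve_auc(tt, y + 55), curve_auc(tt, y))
  expect_error(curve_auc(c(0, 1, 1, 2), c(0, 1, 2, 3)),
               class = "ms_invalid_series")
  expect_error(curve_auc(c(1), c(2)), class = "ms_invalid_series")
})

test_that("compute_deltas pairs strains and subtracts areas", {
  tt <- c(0, 1, 2)
  mk <- function(compound, well, rep, strain, y) {
    data.frame(plate = "P", well = well, compound = compound, conc_rank = 1,
               replicate = rep, strain = strain, time_h = tt, signal = y)
  }
  ps <- rbind(mk("a", "W1", 1, "WT", c(0, 100, 200)),   # area 150... scaled
              mk("a", "W1", 1, "E14Q", c(0, 100, 200)))
  d <- compute_deltas(ps)
  expect_equal(d$delta, 0)
  # areas 150 vs 100 -> +50 (resistance direction)
  ps2 <- rbind(mk("a", "W1", 1, "WT", c(0, 75, 150)),
               mk("a", "W1", 1, "E14Q", c(0, 50, 100)))
  d2 <- compute_deltas(ps2)
  expect_equal(d2$area_wt, 150)
  expect_equal(d2$area_e14q, 100)
  expect_equal(d2$delta, 50)
  # 80 vs 140 -> -60 (susceptibility direction)
  ps3 <- rbind(mk("a", "W1", 1, "WT", c(0, 40, 80)),
               mk("a", "W1", 1, "E14Q", c(0, 70, 140)))
  expect_equal(compute_deltas(ps3)$delta, -60)
  # missing partner names the well
  expect_error(compute_deltas(mk("a", "W9", 1, "WT", c(0, 1, 2))),
               regexp = "W9", class = "ms_pairing_error")
})

test_that("trimmed_mean drops floor(frac * n) per tail", {
  expect_equal(trimmed_mean(rep(4.2, 9), 0.1), 4.2)
  expect_equal(trimmed_mean(c(1:9, 1000), 0.10), 5.5)  # k = 1, mean of 2..9
  expect_equal(trimmed_mean(c(3, 1, 2), 0.10), 2)      # k = 0 -> plain mean
  # agrees with the base trim convention on random data
  set.seed(11)
  for (n in c(5, 20, 101)) {
    x <- rnorm(n)
    expect_equal(trimmed_mean(x, 0.1), mean(x, trim = 0.1))
  }
  expect_error(trimmed_mean(numeric(0)), class = "ms_invalid_argument")
})

test_that("nonhit_sd honours supplied controls and excludes hits in auto mode", {
  # 50 nulls at 0 +- 1, 10 planted hits at +-30
  set.seed(42)
  d <- data.frame(
    well = sprintf("W%02d", 1:60),
    replicate = 1,
    delta = c(rnorm(50), rep(c(30, -30), 5)))
  cfg <- score_config(min_nonhit_wells = 50)
  auto <- nonhit_sd(d, config = cfg)
  expect_false(any(sprintf("W%02d", 51:60) %in% auto$wells))
  expect_equal(auto$sd, sd(d$delta[1:50]), tolerance = 0.15)
  # user-supplied list is authoritative
  sup <- nonhit_sd(d, nonhit_wells = sprintf("W%02d", 1:50), config = cfg)
  expect_equal(sup$sd, sd(d$delta[1:50]))
  expect_identical(sup$method, "supplied")
  # all-equal deltas -> zero SD
  d0 <- data.frame(well = sprintf("W%d", 1:50), replicate = 1, delta = 2)
  expect_equal(nonhit_sd(d0, config = cfg)$sd, 0)
  expect_error(nonhit_sd(d[1:10, ], config = cfg),
               class = "ms_insufficient_controls")
})

test_that("call_well uses strict two-sided cutoffs", {
  cfg <- score_config()
  expect_identical(call_well(0, 0, 1, cfg), 0L)
  expect_identical(call_well(2.5, 0, 1, cfg), 1L)
  expect_identical(call_well(-2.5, 0, 1, cfg), -1L)
  # exactly at the cutoff is NOT a hit ("more than")
  expect_identical(call_well(2.0, 0, 1, cfg), 0L)
  expect_identical(call_well(-2.0, 0, 1, cfg), 0L)
  # sd = 0 degenerates to the sign of any deviation
  expect_identical(call_well(c(1e-9, -1e-9, 0), 0, 0, cfg), c(1L, -1L, 0L))
})

test_that("score_compound sums calls and classifies at the +-3 cutoff", {
  cfg <- score_config()
  s <- score_compound(rep(1L, 8), cfg)
  expect_identical(s$score, 8L)
  expect_identical(s$call, "resistance")
  s <- score_compound(c(rep(-1L, 6), 0L, 0L), cfg)
  expect_identical(s$score, -6L)
  expect_identical(s$call, "susceptibility")
  s <- score_compound(c(1L, 1L, rep(0L, 6)), cfg)
  expect_identical(s$call, "none")
  expect_true(score_compound(c(1L, 1L, 1L), cfg)$partial)
})

test_that("run_screen matches the exhaustive oracle on small panels", {
  for (seed in c(3, 17, 91)) {
    panel <- make_test_panel()
    ps <- gen_plate_set(panel, seed = seed, n_timepoints = 25)
    controls <- attr(ps, "manifest")$control_compounds
    control_wells <- unique(ps$well[ps$compound %in% controls])
    res <- run_screen(ps, score_config(min_nonhit_wells = 40))
    orc <- oracle_screen(ps, control_wells)
    m <- merge(as.data.frame(res), orc, by = "compound")
    expect_equal(m$score, m$call.y, ignore_attr = TRUE)
    expect_identical(m$call.x, m$label)
  }
})

test_that("planted hits are recovered and ranking is deterministic", {
  ps <- gen_plate_set(make_test_panel(), seed = 5, n_timepoints = 25)
  res <- run_screen(ps, score_config(min_nonhit_wells = 40))
  expect_identical(res$compound[1], "hitR")
  expect_identical(res$score[1], 8L)  # 8 affected wells, effect >> cutoff
  # 6 affected wells plant a -6; the two unaffected wells may add chance calls
  expect_identical(res$compound[nrow(res)], "hitS")
  expect_lte(res$score[nrow(res)], -4L)
  expect_identical(res$call[nrow(res)], "susceptibility")
  res2 <- run_screen(ps, score_config(min_nonhit_wells = 40))
  expect_identical(res, res2)
})

test_that("strain-label swap negates every delta and score", {
  ps <- gen_plate_set(make_test_panel(), seed = 23, n_timepoints = 25)
  swapped <- ps
  swapped$strain <- ifelse(ps$strain == "WT", "E14Q", "WT")
  class(swapped) <- class(ps)
  attr(swapped, "manifest") <- attr(ps, "manifest")
  cfg <- score_config(min_nonhit_wells = 40)
  expect_equal(compute_deltas(swapped)$delta, -compute_deltas(ps)$delta)
  r1 <- as.data.frame(run_screen(ps, cfg))
  r2 <- as.data.frame(run_screen(swapped, cfg))
  m <- merge(r1, r2, by = "compound")
  expect_identical(m$score.x, -m$score.y)
})

test_that("adding a constant to every signal leaves deltas unchanged", {
  ps <- gen_plate_set(make_test_panel()[1:15], seed = 7, n_timepoints = 25)
  shifted <- ps
  shifted$signal <- ps$signal + 500
  expect_equal(compute_deltas(shifted)$delta, compute_deltas(ps)$delta)
})

test_that("score magnitude is monotone in the planted effect size", {
  scores <- sapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(es) {
    panel <- c(list(screen_preset("hit", "resistance", effect_size = es,
                                  wells_affected = 8L, noise_cv = 0.02)),
               lapply(sprintf("n%02d", 1:14), screen_preset, noise_cv = 0.02))
    ps <- gen_plate_set(panel, seed = 99, n_timepoints = 25)
    res <- run_screen(ps, score_config(min_nonhit_wells = 40))
    abs(res$score[res$compound == "hit"])
  })
  expect_true(all(diff(scores) >= 0))
  expect_identical(scores[[5]], 8L)
})
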