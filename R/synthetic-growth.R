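# synthetic growth assays: endpoint dose-response plates and checkerboards
#
# Growth follows a logistic curve; the transporter-mediated drug effect only
# kicks in once fermentable carbon runs out and cells lean on the proton
# motive force (onset_time, default 5 h), after which the culture relaxes
# toward a drug-dependent carrying capacity.

#' Growth-model parameters
#'
#' @param carrying_capacity stationary OD600 without drug (default 1.0).
#' @param growth_rate exponential growth rate (per hour, default 0.9).
#' @param lag lag time before growth starts (h, default 1).
#' @param ic50_true true half-inhibitory drug concentration of the reference
#'   (nonfunctional-transporter) strain (uM, default 130).
#' @param hill Hill coefficient of the inhibition curve (default 2).
#' @param onset_time time at which the transporter-mediated drug effect begins
#'   (h, default 5).
#' @param post_onset_rate rate of the relaxation toward the drug-limited
#'   capacity after onset (per hour, default `growth_rate / 2`).
#' @param differential fractional IC50 reduction in the strain whose
#'   functional transporter makes the drug *worse* (default 0.4, i.e. the
#'   susceptible strain's IC50 is 40% lower).
#' @param interaction_alpha drug-drug interaction strength used by
#'   [gen_checkerboard()] when no explicit preset is given (default 0, Loewe
#'   additive).
#' @param od0 inoculation OD600 (default 0.01).
#' @param seed optional recorded seed.
#' @return a `ms_growth_params` list.
#' @export
growth_model_params <- function(carrying_capacity = 1.0, growth_rate = 0.9,
                                lag = 1, ic50_true = 130, hill = 2,
                                onset_time = 5,
                                post_onset_rate = growth_rate / 2,
                                differential = 0.4,
                                interaction_alpha = 0,
                                od0 = 0.01, seed = NULL) {
  for (nm in c("carrying_capacity", "growth_rate", "lag", "ic50_true",
               "onset_time", "post_onset_rate", "od0")) {
    stopifnot_scalar(get(nm), nm, min = 0)
  }
  stopifnot_scalar(hill, "hill", min = 0, strict = TRUE)
  if (differential < 0 || differential >= 1) {
    ms_error("ms_invalid_argument", "differential must be in [0, 1)")
  }
  structure(list(carrying_capacity = carrying_capacity,
                 growth_rate = growth_rate, lag = lag,
                 ic50_true = ic50_true, hill = hill,
                 onset_time = onset_time, post_onset_rate = post_onset_rate,
                 differential = differential,
                 interaction_alpha = interaction_alpha,
                 od0 = od0, seed = seed),
            class = "ms_growth_params")
}

logistic_od <- function(od0, K, r, t) {
  K / (1 + (K / od0 - 1) * exp(-r * pmax(t, 0)))
}

# deterministic endpoint OD of the two-phase logistic model
endpoint_od_model <- function(conc, ic50, params, endpoint_h) {
  p <- params
  inh <- 1 / (1 + (conc / ic50)^p$hill)
  od_onset <- logistic_od(p$od0, p$carrying_capacity, p$growth_rate,
                          p$onset_time - p$lag)
  k_eff <- pmax(p$carrying_capacity * inh, 1e-4)
  logistic_od(od_onset, k_eff, p$post_onset_rate, endpoint_h - p$onset_time)
}

strain_ic50 <- function(params, strain, mode_effect) {
  base <- params$ic50_true
  d <- params$differential
  switch(mode_effect,
         none = base,
         susceptibility = if (strain == "WT") base * (1 - d) else base,
         resistance = if (strain == "WT") base else base * (1 - d))
}

#' Generate a synthetic endpoint growth plate
#'
#' Logistic growth with a drug-dependent post-onset carrying capacity; for a
#' susceptibility compound the functional (WT) strain is hit at a
#' `1 - differential` fraction of the reference IC50 (and symmetrically the
#' nonfunctional strain for a resistance compound).  Endpoint OD600 is read at
#' `endpoint_h` with multiplicative measurement noise.
#'
#' @param params a [growth_model_params()].
#' @param drug_grid drug concentrations (uM, non-empty, should include 0).
#' @param strain `"WT"` or `"E14Q"`.
#' @param mode_effect `"susceptibility"`, `"resistance"` or `"none"`.
#' @param endpoint_h endpoint read time (h, default 18).
#' @param n_replicates replicate wells per concentration (default 3).
#' @param noise_cv multiplicative OD noise (default 0.02).
#' @param seed integer seed.
#' @param full_curves also attach 5-min-resolution growth curves as the
#'   `curves` attribute.
#' @return data frame of class `ms_dose_plate`: `conc_uM`, `replicate`,
#'   `od600`, `strain`; `truth` attribute records the planted strain IC50.
#' @export
gen_growth_plate <- function(params = growth_model_params(),
                             drug_grid = c(0, 6.25, 12.5, 25, 50, 100, 200, 400),
                             strain = c("WT", "E14Q"),
                             mode_effect = c("susceptibility", "resistance",
                                             "none"),
                             endpoint_h = 18, n_replicates = 3L,
                             noise_cv = 0.02, seed = NULL,
                             full_curves = FALSE) {
  strain <- match.arg(strain)
  mode_effect <- match.arg(mode_effect)
  if (!length(drug_grid)) ms_error("ms_invalid_grid", "drug_grid is empty")
  if (any(drug_grid < 0)) ms_error("ms_invalid_grid", "drug_grid must be >= 0")
  stopifnot_scalar(endpoint_h, "endpoint_h", min = 0, strict = TRUE)
  ic50 <- strain_ic50(params, strain, mode_effect)
  od_true <- endpoint_od_model(drug_grid, ic50, params, endpoint_h)
  seed <- seed %||% params$seed
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(conc_uM = drug_grid, replicate = r,
                 od600 = od_true * exp(stats::rnorm(length(drug_grid), 0,
                                                    noise_cv)),
                 strain = strain)
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- list(ic50 = ic50, mode_effect = mode_effect,
                               params = params, seed = seed)
    if (full_curves) {
      tt <- seq(0, endpoint_h, by = 1 / 12)
      pre <- logistic_od(params$od0, params$carrying_capacity,
                         params$growth_rate, tt - params$lag)
      curves <- lapply(drug_grid, function(cc) {
        inh <- 1 / (1 + (cc / ic50)^params$hill)
        k_eff <- pmax(params$carrying_capacity * inh, 1e-4)
        od_onset <- logistic_od(params$od0, params$carrying_capacity,
                                params$growth_rate,
                                params$onset_time - params$lag)
        post <- logistic_od(od_onset, k_eff, params$post_onset_rate,
                            tt - params$onset_time)
        data.frame(conc_uM = cc, time_h = tt,
                   od600 = ifelse(tt < params$onset_time, pre, post))
      })
      attr(out, "curves") <- do.call(rbind, curves)
    }
    class(out) <- c("ms_dose_plate", "data.frame")
    out
  })
}

#' Generate a paired WT/E14Q dose-response plate set
#'
#' Convenience wrapper around [gen_growth_plate()] producing both strains
#' under one master seed (per-strain seeds are derived, so the pair shares a
#' design but not noise).
#'
#' @inheritParams gen_growth_plate
#' @param seed master seed.
#' @return named list with `WT` and `E14Q` `ms_dose_plate`s.
#' @export
gen_growth_pair <- function(params = growth_model_params(),
                            drug_grid = c(0, 6.25, 12.5, 25, 50, 100, 200, 400),
                            mode_effect = "susceptibility",
                            endpoint_h = 18, n_replicates = 3L,
                            noise_cv = 0.02, seed = NULL) {
  list(WT = gen_growth_plate(params, drug_grid, "WT", mode_effect,
                             endpoint_h, n_replicates, noise_cv,
                             seed = derive_seed(seed, 1L)),
       E14Q = gen_growth_plate(params, drug_grid, "E14Q", mode_effect,
                               endpoint_h, n_replicates, noise_cv,
                               seed = derive_seed(seed, 2L)))
}

# inhibition surface for two drugs in MIC-fraction coordinates
interaction_surface <- function(a, b, alpha, hill) {
  e <- a + b + alpha * a * b
  1 / (1 + e^hill)
}

#' Generate a synthetic checkerboard plate
#'
#' Endpoint OD over a two-drug grid.  Inhibition follows a sharp sigmoid in
#' the combined Loewe-style dose index `a + b + alpha * a * b`, with `a`, `b`
#' the concentrations in units of each drug's true single-agent MIC.
#' `alpha > 0` plants synergy (the growth/no-growth interface steps inward),
#' `alpha = 0` additivity, `alpha < 0` antagonism.  Named interaction presets
#' use the packaged calibrations (`synergy` alpha = 20, `indifferent`
#' alpha = 16 with a higher partner MIC, `antagonist` alpha = -0.9).
#'
#' @param gridA drug A (antibiotic) concentrations, monotone increasing,
#'   including 0.
#' @param gridB drug B (adjuvant) concentrations, ditto.
#' @param mic_a,mic_b true single-agent MICs (uM); defaults place drug A's MIC
#'   between the two top grid concentrations and drug B's near the top of its
#'   grid.
#' @param interaction `"synergy"`, `"indifferent"`, `"antagonist"`, or `NULL`
#'   to use `alpha` directly.
#' @param alpha explicit interaction strength (overridden by `interaction`).
#' @param hill sharpness of the growth/no-growth transition (default 12).
#' @param od_max background OD600 (default 0.6).
#' @param n_replicates replicate plates (default 3).
#' @param noise_cv multiplicative OD noise (default 0.03).
#' @param seed integer seed.
#' @return object of class `ms_checkerboard`: list with `gridA`, `gridB`,
#'   `od` (nA x nB matrix, replicate average), `replicates` (list of
#'   matrices), `compound_a`, `compound_b`, `truth`.
#' @export
gen_checkerboard <- function(gridA, gridB,
                             mic_a = 0.7 * max(gridA),
                             mic_b = 0.45 * max(gridB),
                             interaction = NULL, alpha = 0,
                             hill = 12, od_max = 0.6,
                             n_replicates = 3L, noise_cv = 0.03,
                             seed = NULL,
                             compound_a = "drugA", compound_b = "drugB") {
  for (g in list(gridA, gridB)) {
    if (length(g) < 2L || any(diff(g) <= 0) || g[1L] != 0) {
      ms_error("ms_invalid_design",
               "grids must be monotone increasing and include 0 (MIC reference)")
    }
  }
  if (!is.null(interaction)) {
    alpha <- switch(match.arg(interaction,
                              c("synergy", "indifferent", "antagonist")),
                    synergy = 20, indifferent = 16, antagonist = -0.9)
  }
  g_true <- od_max * interaction_surface(outer(gridA / mic_a, rep(1, length(gridB))),
                                         outer(rep(1, length(gridA)), gridB / mic_b),
                                         alpha, hill)
  with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      g_true * matrix(exp(stats::rnorm(length(g_true), 0, noise_cv)),
                      nrow = nrow(g_true))
    })
    od <- Reduce(`+`, reps) / n_replicates
    dimnames(od) <- list(A = gridA, B = gridB)
    structure(list(gridA = gridA, gridB = gridB, od = od, replicates = reps,
                   compound_a = compound_a, compound_b = compound_b,
                   truth = list(mic_a = mic_a, mic_b = mic_b, alpha = alpha,
                                hill = hill, seed = seed)),
              class = "ms_checkerboard")
  })
}
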