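# packaged study presets: the generator parameterisations and recorded seeds
# that emulate each reported experiment, with planted ground truth

#' Packaged synthetic presets
#'
#' Named parameterisations of the synthetic-data generators emulating the
#' study's experiments, each with a recorded seed and planted truth:
#'
#' * `"mv_screen"` -- methyl-viologen-like resistance compound, all 8 wells
#'   affected (expected screen score +8), inside a 20-compound plate set.
#' * `"harmane_screen"` -- harmane-like susceptibility compound, 6 of 8 wells
#'   affected (expected score -6), same plate set.
#' * `"harmane_binding"` -- quench titration, Kd 29 uM, dimer 10 uM, 12-point
#'   grid to 800 uM, 1% noise, 3 replicates.
#' * `"harmane_gating"` -- drug-gated proton-uniport transporter, Km 5 uM;
#'   peak currents over 0.5--50 uM, 3 sensors, 5% noise.
#' * `"metpp_antiport"`, `"harmane_proton_uniport"`, `"cation_uniport"`,
#'   `"neutral_uniport"`, `"inactive_control"` -- SSME transporter
#'   parameterisations for the mode classifier.
#' * `"harmane_growth"` -- paired WT/E14Q endpoint dose-response with a
#'   planted 40% IC50 reduction in the WT (susceptible) strain.
#' * `"kanamycin_harmane"` -- checkerboard synergy preset (kanamycin 0--80 uM
#'   x harmane 0--1150 uM) whose analysis yields a mean FIC of 0.375.
#' * `"tetracycline_harmane"` -- indifferent preset (tetracycline 0--16 uM)
#'   yielding a mean FIC of 0.58.
#'
#' @param name preset name (see above); `ms_presets()` lists all.
#' @return a list with the generator name, its arguments, the recorded `seed`
#'   and the planted `truth`.
#' @seealso [generate_preset()]
#' @export
ms_preset <- function(name) {
  presets <- list(
    mv_screen = list(
      generator = "gen_plate_set",
      args = list(presets = screen_panel(), seed = 101L),
      truth = list(compound = "MV", score = 8L, call = "resistance")),
    harmane_screen = list(
      generator = "gen_plate_set",
      args = list(presets = screen_panel(), seed = 101L),
      truth = list(compound = "harmane", score = -6L,
                   call = "susceptibility")),
    harmane_binding = list(
      generator = "gen_titration",
      args = list(Kd = 29, F_EH = 0.2, F_E = 1.0, E_T = 10,
                  noise_sd = 0.01, seed = 201L),
      truth = list(Kd = 29, n_replicates = 3L)),
    harmane_gating = list(
      generator = "gen_gating_data",
      args = list(params = transporter_params("proton_uniport", Km_gate = 5,
                                              z_D = 0),
                  concentrations = c(0.5, 1, 2, 5, 10, 20, 35, 50),
                  n_sensors = 3L, noise_frac = 0.05, seed = 301L),
      truth = list(Km = 5)),
    metpp_antiport = list(
      generator = "transporter_params",
      args = list(mode = "antiport", n_H = 2, n_D = 1, z_D = 1),
      truth = list(mode = "antiport")),
    harmane_proton_uniport = list(
      generator = "transporter_params",
      args = list(mode = "proton_uniport", z_D = 0, Km_gate = 5),
      truth = list(mode = "proton_uniport")),
    cation_uniport = list(
      generator = "transporter_params",
      args = list(mode = "drug_uniport", z_D = 1),
      truth = list(mode = "drug_uniport")),
    neutral_uniport = list(
      generator = "transporter_params",
      args = list(mode = "drug_uniport", z_D = 0),
      truth = list(mode = "drug_uniport", silent = TRUE)),
    inactive_control = list(
      generator = "transporter_params",
      args = list(mode = "inactive"),
      truth = list(mode = "inactive")),
    harmane_growth = list(
      generator = "gen_growth_pair",
      args = list(params = growth_model_params(ic50_true = 130,
                                               differential = 0.4),
                  mode_effect = "susceptibility", seed = 401L),
      truth = list(ic50_wt = 78, ic50_e14q = 130, percent_lower = 40)),
    kanamycin_harmane = list(
      generator = "gen_checkerboard",
      args = list(gridA = c(0, 0.625, 1.25, 2.5, 5, 10, 20, 40, 80),
                  gridB = c(0, 9, 18, 36, 72, 144, 287.5, 575, 1150),
                  mic_a = 20, mic_b = 500, interaction = "synergy",
                  seed = 501L,
                  compound_a = "kanamycin", compound_b = "harmane"),
      truth = list(fic = 0.375, call = "synergistic")),
    tetracycline_harmane = list(
      generator = "gen_checkerboard",
      args = list(gridA = c(0, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16),
                  gridB = c(0, 9, 18, 36, 72, 144, 287.5, 575, 1150),
                  mic_a = 5.6, mic_b = 575, interaction = "indifferent",
                  seed = 502L,
                  compound_a = "tetracycline", compound_b = "harmane"),
      truth = list(fic = 0.58, call = "indifferent")))
  if (!name %in% names(presets)) {
    ms_error("ms_invalid_preset", sprintf(
      "unknown preset '%s'; see ?ms_preset for the available names", name))
  }
  c(presets[[name]], list(name = name, seed = presets[[name]]$args$seed))
}

#' @rdname ms_preset
#' @export
ms_presets <- function() {
  c("mv_screen", "harmane_screen", "harmane_binding", "harmane_gating",
    "metpp_antiport", "harmane_proton_uniport", "cation_uniport",
    "neutral_uniport", "inactive_control", "harmane_growth",
    "kanamycin_harmane", "tetracycline_harmane")
}

# the 20-compound screen panel: two planted hits in a field of inactive
# compounds, enough wells (80 per replicate) for the non-hit SD
screen_panel <- function(noise_cv = 0.02) {
  c(list(
    screen_preset("MV", "resistance", effect_size = 0.5,
                  wells_affected = 8L, noise_cv = noise_cv),
    screen_preset("harmane", "susceptibility", effect_size = 0.4,
                  wells_affected = 6L, noise_cv = noise_cv)),
    lapply(sprintf("compound-%02d", 1:18), screen_preset,
           noise_cv = noise_cv))
}

#' Generate the data for a packaged preset
#'
#' Runs the preset's generator with its recorded arguments.  `seed` overrides
#' the recorded seed (all packaged planted truths are robust to the seed
#' choice by construction).
#'
#' @param name preset name (see [ms_preset()]).
#' @param seed optional seed override.
#' @return whatever the preset's generator returns, with the preset definition
#'   attached as the `preset` attribute.
#' @examples
#' cb <- generate_preset("kanamycin_harmane")
#' compute_fic(cb)
#' @export
generate_preset <- function(name, seed = NULL) {
  p <- ms_preset(name)
  args <- p$args
  if (!is.null(seed) && "seed" %in% names(args)) args$seed <- seed
  out <- do.call(p$generator, args, envir = asNamespace("modeswitch"))
  attr(out, "preset") <- p
  out
}
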