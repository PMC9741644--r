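# synthetic phenotype-microarray generator: paired WT/E14Q respiration curves

#' Define a compound preset for the synthetic phenotype screen
#'
#' A preset plants a known differential effect for one compound in a synthetic
#' plate set.  Each compound occupies 4 wells per plate set (one per
#' concentration rank) in each of 2 replicate plate sets, i.e. 8 scored wells.
#' `wells_affected` says how many of those 8 well/replicate slots actually
#' show the effect (filled replicate 1 first, then replicate 2), emulating
#' compounds whose lower concentration ranks do not elicit a phenotype.
#'
#' @param compound compound label.
#' @param effect_direction `"resistance"`, `"susceptibility"` or `"none"`.
#' @param effect_size fractional change of the affected strain-pair AUC
#'   (unitless, >= 0; must be 0 when `effect_direction = "none"`).  For
#'   resistance the WT curve amplitude is raised by this fraction relative to
#'   E14Q in affected wells; for susceptibility the E14Q amplitude is raised
#'   (equivalently, functional transporter hurts the cells).
#' @param wells_affected integer in 0..8.
#' @param noise_cv coefficient of variation of the multiplicative noise, used
#'   both per timepoint and as a per-well amplitude jitter.
#' @param seed optional preset-specific seed (recorded in the manifest).
#' @return a `ms_screen_preset` list.
#' @seealso [gen_plate_set()]
#' @export
screen_preset <- function(compound,
                          effect_direction = c("none", "resistance",
                                               "susceptibility"),
                          effect_size = 0,
                          wells_affected = 0L,
                          noise_cv = 0.02,
                          seed = NULL) {
  effect_direction <- match.arg(effect_direction)
  if (!is_scalar_number(wells_affected) || wells_affected < 0 ||
      wells_affected > 8 || wells_affected != round(wells_affected)) {
    ms_error("ms_invalid_preset", sprintf(
      "wells_affected must be an integer in [0, 8] (got %s) for compound '%s'",
      format(wells_affected), compound))
  }
  stopifnot_scalar(noise_cv, "noise_cv", min = 0)
  stopifnot_scalar(effect_size, "effect_size", min = 0)
  if (effect_direction == "none" && effect_size != 0) {
    ms_error("ms_invalid_preset",
             "effect_direction = 'none' requires effect_size = 0")
  }
  structure(list(compound = as.character(compound),
                 effect_direction = effect_direction,
                 effect_size = effect_size,
                 wells_affected = as.integer(wells_affected),
                 noise_cv = noise_cv,
                 seed = seed),
            class = "ms_screen_preset")
}

# Gompertz respiration curve in OmniLog-like arbitrary units; the exact shape
# is irrelevant to the AUC differential, it just has to saturate.
gompertz_curve <- function(time_h, amplitude, displacement = 5, rate = 0.3) {
  amplitude * exp(-displacement * exp(-rate * time_h))
}

#' Generate a synthetic phenotype-microarray plate set
#'
#' Builds paired WT/E14Q kinetic respiration curves for a panel of compound
#' presets: 4 wells per compound per plate set, read on a shared time grid
#' (default every 15 min for 24 h).  Differential effects are planted by
#' scaling the affected strain's curve amplitude; noise is multiplicative
#' Gaussian per timepoint plus a lognormal per-well amplitude jitter, both at
#' the preset's `noise_cv`.  Identical `seed` gives bit-identical output.
#'
#' @param presets list of [screen_preset()] objects (each compound gets 4
#'   wells per plate set).
#' @param n_replicates number of replicate plate sets (default 2).
#' @param n_timepoints points on the 0--24 h grid (default 97 = 15-min reads).
#' @param seed integer seed; defaults to the first preset seed if any.
#' @param amplitude baseline curve amplitude (arbitrary units).
#' @return a long-format data frame of class `ms_plate_set` with columns
#'   `plate, well, compound, conc_rank, replicate, strain, time_h, signal` and
#'   a `manifest` attribute recording presets, seed, planted truth and the
#'   control (no-effect) wells.
#' @examples
#' ps <- gen_plate_set(list(
#'   screen_preset("MV", "resistance", 0.5, 8),
#'   screen_preset("water")), seed = 1)
#' head(ps)
#' @export
gen_plate_set <- function(presets, n_replicates = 2L, n_timepoints = 97L,
                          seed = NULL, amplitude = 200) {
  if (inherits(presets, "ms_screen_preset")) presets <- list(presets)
  if (!length(presets) || !all(vapply(presets, inherits, TRUE,
                                      "ms_screen_preset"))) {
    ms_error("ms_invalid_preset", "presets must be screen_preset() objects")
  }
  if (n_replicates < 1) {
    ms_error("ms_invalid_argument", "n_replicates must be >= 1")
  }
  seed <- seed %||% presets[[1L]]$seed
  time_h <- seq(0, 24, length.out = n_timepoints)
  base_curve <- gompertz_curve(time_h, amplitude)

  with_seed(seed, {
    rows <- vector("list", length(presets) * 4L * n_replicates * 2L)
    ri <- 0L
    for (ci in seq_along(presets)) {
      p <- presets[[ci]]
      # order of the 8 (replicate, conc_rank) slots used to fill wells_affected
      slots <- expand.grid(conc_rank = 1:4, replicate = seq_len(n_replicates))
      affected <- seq_len(nrow(slots)) <= p$wells_affected
      for (k in seq_len(nrow(slots))) {
        rep_id <- slots$replicate[k]
        rank <- slots$conc_rank[k]
        well_id <- sprintf("W%03d", (ci - 1L) * 4L + rank)
        boost <- if (affected[k]) p$effect_size else 0
        amp_wt <- amplitude * exp(stats::rnorm(1, 0, p$noise_cv))
        amp_eq <- amplitude * exp(stats::rnorm(1, 0, p$noise_cv))
        if (p$effect_direction == "resistance") amp_wt <- amp_wt * (1 + boost)
        if (p$effect_direction == "susceptibility") amp_eq <- amp_eq * (1 + boost)
        for (strain in c("WT", "E14Q")) {
          amp <- if (strain == "WT") amp_wt else amp_eq
          sig <- gompertz_curve(time_h, amp) *
            exp(stats::rnorm(n_timepoints, 0, p$noise_cv))
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            plate = sprintf("PM-rep%d", rep_id),
            well = well_id,
            compound = p$compound,
            conc_rank = rank,
            replicate = rep_id,
            strain = strain,
            time_h = time_h,
            signal = sig)
        }
      }
    }
    out <- do.call(rbind, rows[seq_len(ri)])
    rownames(out) <- NULL
    controls <- vapply(presets, function(p) p$effect_direction == "none", TRUE)
    attr(out, "manifest") <- list(
      presets = presets,
      seed = seed,
      n_replicates = n_replicates,
      baseline_auc = trapz_strict(time_h, base_curve - base_curve[1L]),
      control_compounds = vapply(presets[controls], `[[`, "", "compound"),
      truth = data.frame(
        compound = vapply(presets, `[[`, "", "compound"),
        effect_direction = vapply(presets, `[[`, "", "effect_direction"),
        effect_size = vapply(presets, `[[`, 0, "effect_size"),
        wells_affected = vapply(presets, `[[`, 0L, "wells_affected")))
    class(out) <- c("ms_plate_set", "data.frame")
    out
  })
}
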