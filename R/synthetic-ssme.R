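# thermodynamic-relaxation simulator for solid-supported membrane
# electrophysiology (SSME) transport currents
#
# The instrument reports the current of proteoliposomes adsorbed on a gold
# sensor while buffers are exchanged.  We model the total transported charge
# as proportional to (net charge moved per cycle) x (log-gradient
# thermodynamic drive) x (drug-gating occupancy), relaxing with a single
# exponential once the external buffer arrives.  This is the minimal model
# that reproduces the qualitative sign/magnitude pattern expected for each
# transport mode under the assay's gradient conditions.

#' Transporter parameters for the SSME simulator
#'
#' @param mode transport mode: `"antiport"` (n_H protons in per n_D drugs
#'   out), `"symport"` (co-transport inward), `"drug_uniport"`,
#'   `"proton_uniport"` (drug-gated proton leak), or `"inactive"`
#'   (transport-dead control).
#' @param n_H protons per cycle (default 2 for antiport, 1 otherwise).
#' @param n_D drugs per cycle (default 1; forced 0 for proton uniport).
#' @param z_D drug charge in elementary charges (0 or +1 typically).
#' @param Km_gate drug half-saturation of gating (uM), used by proton uniport.
#' @param kappa charge scale (nC per unit log-gradient drive).
#' @param tau relaxation time of the transport current (s).
#' @param leak0 drug-independent background charge scale (nC per unit proton
#'   log-gradient), present for every mode including `inactive`.
#' @param gating_side which side's drug concentration gates the proton-uniport
#'   cycle: `"max"` (default; drug on either face can gate, reproducing the
#'   gradient-invariant signal observed for harmane) or `"min"` (requires drug
#'   on both faces).
#' @return a `ms_transporter_params` list.
#' @export
transporter_params <- function(mode = c("antiport", "symport", "drug_uniport",
                                        "proton_uniport", "inactive"),
                               n_H = NULL, n_D = NULL, z_D = 1,
                               Km_gate = 5, kappa = 1, tau = 0.2,
                               leak0 = 0.02,
                               gating_side = c("max", "min")) {
  mode <- match.arg(mode)
  gating_side <- match.arg(gating_side)
  n_H <- n_H %||% switch(mode, antiport = 2, inactive = 0,
                         drug_uniport = 0, 1)
  n_D <- n_D %||% switch(mode, proton_uniport = 0, inactive = 0, 1)
  if (n_H < 0 || n_D < 0) ms_error("ms_invalid_argument", "n_H, n_D must be >= 0")
  if (mode == "proton_uniport" && n_D != 0) {
    ms_error("ms_invalid_argument", "proton uniport transports no drug (n_D = 0)")
  }
  stopifnot_scalar(tau, "tau", min = 0, strict = TRUE)
  stopifnot_scalar(kappa, "kappa", min = 0)
  stopifnot_scalar(Km_gate, "Km_gate", min = 0, strict = TRUE)
  structure(list(mode = mode, n_H = n_H, n_D = n_D, z_D = z_D,
                 Km_gate = Km_gate, kappa = kappa, tau = tau, leak0 = leak0,
                 gating_side = gating_side),
            class = "ms_transporter_params")
}

#' Gradient condition for an SSME measurement
#'
#' @param label condition label: `"no_drug"`, `"no_gradient"`,
#'   `"with_proton_gradient"` (drug gradient aligned with the inward proton
#'   gradient, i.e. drug high outside) or `"against_proton_gradient"`
#'   (drug high inside, the orientation that favours antiport).
#' @param pH_in,pH_out internal/external pH (defaults 7.3 / 7.0: a 2-fold
#'   inward proton gradient).
#' @param drug_in,drug_out internal/external drug concentration (uM).
#' @return a `ms_gradient_condition` list.
#' @export
gradient_condition <- function(label = c("no_drug", "no_gradient",
                                         "with_proton_gradient",
                                         "against_proton_gradient"),
                               pH_in = 7.3, pH_out = 7.0,
                               drug_in = 0, drug_out = 0) {
  label <- match.arg(label)
  if (drug_in < 0 || drug_out < 0) {
    ms_error("ms_invalid_argument", "drug concentrations must be >= 0")
  }
  if (label == "no_drug" && (drug_in > 0 || drug_out > 0)) {
    ms_error("ms_invalid_argument", "no_drug condition must have zero drug")
  }
  structure(list(label = label, pH_in = pH_in, pH_out = pH_out,
                 drug_in = drug_in, drug_out = drug_out),
            class = "ms_gradient_condition")
}

#' The standard four-condition gradient panel
#'
#' Reproduces the assay design: a constant 2-fold inward proton gradient
#' (pH 7.0 outside / 7.3 inside) combined with (i) no drug, (ii) drug with no
#' gradient (equal on both sides), (iii) a 16-fold drug gradient aligned with
#' the proton gradient, and (iv) the same gradient opposed to it.
#'
#' @param drug_high,drug_low high/low drug concentrations (uM; defaults 8 and
#'   0.5, a 16-fold gradient).
#' @param pH_in,pH_out internal/external pH.
#' @return named list of four [gradient_condition()]s.
#' @export
standard_gradient_conditions <- function(drug_high = 8, drug_low = 0.5,
                                         pH_in = 7.3, pH_out = 7.0) {
  list(
    no_drug = gradient_condition("no_drug", pH_in, pH_out, 0, 0),
    no_gradient = gradient_condition("no_gradient", pH_in, pH_out,
                                     drug_high, drug_high),
    with_proton_gradient = gradient_condition("with_proton_gradient",
                                              pH_in, pH_out,
                                              drug_low, drug_high),
    against_proton_gradient = gradient_condition("against_proton_gradient",
                                                 pH_in, pH_out,
                                                 drug_high, drug_low))
}

#' Fold-gradients of a condition
#'
#' @param cond a [gradient_condition()].
#' @return list with `proton_fold` = \[H+\]out / \[H+\]in = 10^(pH_in - pH_out)
#'   and `drug_fold` = max(drug) / min(drug) (`NA` without drug).
#' @examples
#' gradient_folds(standard_gradient_conditions()$with_proton_gradient)
#' @export
gradient_folds <- function(cond) {
  dmin <- min(cond$drug_in, cond$drug_out)
  list(proton_fold = 10^(cond$pH_in - cond$pH_out),
       drug_fold = if (dmin > 0) max(cond$drug_in, cond$drug_out) / dmin
                   else NA_real_)
}

#' Net inward elementary charge per transport cycle
#'
#' Stoichiometric bookkeeping for one forward (proton-downhill) cycle:
#' antiport moves `n_H` protons in and `n_D` drugs out
#' (`q = n_H - n_D * z_D`), symport moves both in (`q = n_H + n_D * z_D`),
#' drug uniport moves only drug (`q = n_D * z_D`), proton uniport only
#' protons (`q = n_H`), and an inactive transporter moves nothing.
#'
#' @param params a [transporter_params()].
#' @return net inward charge per cycle (elementary charges).
#' @examples
#' net_charge_per_cycle(transporter_params("antiport"))          # 2 - 1 = 1
#' net_charge_per_cycle(transporter_params("symport", n_H = 1))  # 1 + 1 = 2
#' @export
net_charge_per_cycle <- function(params) {
  with(params, switch(mode,
    antiport = n_H - n_D * z_D,
    symport = n_H + n_D * z_D,
    drug_uniport = n_D * z_D,
    proton_uniport = n_H,
    inactive = 0))
}

# log-gradient thermodynamic drive restricted to the transported species.
# Drug terms use a 1e-3 uM floor so a one-sided drug gradient stays finite.
log_drive <- function(params, cond) {
  ln_h <- log(10^(cond$pH_in - cond$pH_out))  # ln([H+]out / [H+]in)
  floor_um <- 1e-3
  drug_present <- max(cond$drug_in, cond$drug_out) > 0
  ln_d <- if (drug_present) {
    log(max(cond$drug_out, floor_um) / max(cond$drug_in, floor_um))
  } else 0
  with(params, switch(mode,
    antiport = if (drug_present) n_H * ln_h - n_D * ln_d else 0,
    symport = if (drug_present) n_H * ln_h + n_D * ln_d else 0,
    drug_uniport = n_D * ln_d,
    proton_uniport = n_H * ln_h,
    inactive = 0))
}

# drug-gating occupancy (proton uniport only)
gating_occupancy <- function(params, cond) {
  if (params$mode != "proton_uniport") return(1)
  d <- if (params$gating_side == "max") max(cond$drug_in, cond$drug_out)
       else min(cond$drug_in, cond$drug_out)
  d / (params$Km_gate + d)
}

#' Steady-state transported charge under a gradient condition
#'
#' `Q = kappa * q_net * D * g + leak`, where `q_net` is the net charge per
#' cycle, `D` the log-gradient drive over the transported species, `g` the
#' drug-gating occupancy, and `leak = leak0 * ln([H+]out/[H+]in)` a small
#' drug-independent proton background present for every mode.
#'
#' @param params a [transporter_params()].
#' @param cond a [gradient_condition()].
#' @return steady-state charge (nC), signed positive for net positive charge
#'   moving into the liposome.
#' @export
steady_state_charge <- function(params, cond) {
  ln_h <- log(10^(cond$pH_in - cond$pH_out))
  q_mode <- params$kappa * net_charge_per_cycle(params) *
    log_drive(params, cond) * gating_occupancy(params, cond)
  q_mode + params$leak0 * ln_h
}

#' Simulate one SSME current trace
#'
#' Emulates the three acquisition stages: perfusion with internal buffer
#' (flat baseline), perfusion with external buffer (transport transient:
#' `I(t) = (Q_ss / tau) * exp(-t / tau)`), and re-equilibration with internal
#' buffer.  Gaussian sampling noise and a constant sensor offset are added to
#' every point.
#'
#' @param params a [transporter_params()].
#' @param cond a [gradient_condition()].
#' @param duration length of the external (transport) phase in s.
#' @param dt sampling interval in s (must be < `duration`).
#' @param noise_sd additive current noise SD (nA).
#' @param seed integer seed.
#' @param t_internal length of each internal phase (s; first one supplies the
#'   baseline window).
#' @param offset_nA constant sensor current offset (nA), removed downstream by
#'   baseline subtraction.
#' @param sensor_id label carried into measurements.
#' @return object of class `ms_ssme_trace`: `time`, `current`, `phases`
#'   (data frame phase/t_start/t_end), `condition`, `sensor_id`, and the
#'   noiseless `Q_ss` used (for reference, not consumed by the analysis).
#' @examples
#' tr <- simulate_ssme_trace(transporter_params("antiport"),
#'                           standard_gradient_conditions()$no_gradient,
#'                           seed = 1)
#' integrate_trace(tr)
#' @export
simulate_ssme_trace <- function(params, cond, duration = 2, dt = 0.005,
                                noise_sd = 0.01, seed = NULL,
                                t_internal = 0.5, offset_nA = 0.05,
                                sensor_id = "sensor-1") {
  stopifnot_scalar(duration, "duration", min = 0, strict = TRUE)
  stopifnot_scalar(dt, "dt", min = 0, strict = TRUE)
  if (dt >= duration) {
    ms_error("ms_invalid_sampling", "dt must be smaller than duration")
  }
  q_ss <- steady_state_charge(params, cond)
  t_total <- 2 * t_internal + duration
  time <- seq(0, t_total, by = dt)
  ext_start <- t_internal
  ext_end <- t_internal + duration
  current <- rep(offset_nA, length(time))
  in_ext <- time >= ext_start & time < ext_end
  current[in_ext] <- current[in_ext] +
    (q_ss / params$tau) * exp(-(time[in_ext] - ext_start) / params$tau)
  with_seed(seed, {
    current <- current + stats::rnorm(length(time), 0, noise_sd)
    structure(list(
      time = time, current = current,
      phases = data.frame(
        phase = c("internal_1", "external", "internal_2"),
        t_start = c(0, ext_start, ext_end),
        t_end = c(ext_start, ext_end, t_total)),
      condition = cond, sensor_id = sensor_id, Q_ss = q_ss),
      class = "ms_ssme_trace")
  })
}

#' Simulate a full SSME experiment
#'
#' One trace per (condition, sensor), with per-trace seeds derived from
#' `seed`.
#'
#' @param params a [transporter_params()].
#' @param conditions named list of [gradient_condition()]s (default the
#'   standard four-condition panel).
#' @param n_sensors replicate sensors per condition (default 3).
#' @param seed master seed.
#' @inheritParams simulate_ssme_trace
#' @return list of class `ms_ssme_experiment`: `traces` (list of traces),
#'   `params`, `conditions`.
#' @export
simulate_ssme_experiment <- function(params,
                                     conditions = standard_gradient_conditions(),
                                     n_sensors = 3L, seed = NULL,
                                     duration = 2, dt = 0.005,
                                     noise_sd = 0.01, ...) {
  traces <- list()
  k <- 0L
  for (cond in conditions) {
    for (s in seq_len(n_sensors)) {
      k <- k + 1L
      traces[[k]] <- simulate_ssme_trace(
        params, cond, duration = duration, dt = dt, noise_sd = noise_sd,
        seed = derive_seed(seed, k), sensor_id = sprintf("sensor-%d", s), ...)
    }
  }
  structure(list(traces = traces, params = params, conditions = conditions),
            class = "ms_ssme_experiment")
}
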