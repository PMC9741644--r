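# SSME trace processing: baseline subtraction, charge integration, gating
# kinetics, and rule-based transport-mode classification

# integration windows include both phase boundaries so that contiguous phases
# tile the trace without dropping a trapezoid panel
phase_window <- function(trace, phase) {
  ph <- trace$phases[trace$phases$phase == phase, ]
  if (!nrow(ph)) {
    ms_error("ms_phase_error", sprintf("trace lacks the '%s' phase", phase))
  }
  trace$time >= ph$t_start[1L] & trace$time <= ph$t_end[1L]
}

#' Baseline current of a trace
#'
#' Mean current over the final `window` seconds of the initial
#' internal-buffer perfusion.
#'
#' @param trace a `ms_ssme_trace` (from [simulate_ssme_trace()] or
#'   [read_ssme_trace()]).
#' @param window baseline window length in s (default 0.1 = 100 ms).
#' @return baseline current (nA).
#' @export
baseline_current <- function(trace, window = 0.1) {
  ph <- trace$phases[trace$phases$phase == "internal_1", ]
  if (!nrow(ph)) ms_error("ms_phase_error", "trace lacks the internal_1 phase")
  if (ph$t_end[1L] - ph$t_start[1L] < window) {
    ms_error("ms_baseline_window_error", sprintf(
      "internal_1 phase (%.3f s) is shorter than the %.3f s baseline window",
      ph$t_end[1L] - ph$t_start[1L], window))
  }
  sel <- trace$time >= (ph$t_end[1L] - window) & trace$time < ph$t_end[1L]
  mean(trace$current[sel])
}

#' Integrate a trace into a transported charge
#'
#' Subtracts the internal-phase baseline and trapezoidally integrates the
#' current over the external (transport) phase.  With current in nA and time
#' in s the charge is in nC.  No resampling or filtering is applied.
#'
#' @inheritParams baseline_current
#' @return list of class `ms_charge_measurement`: `condition` label,
#'   `total_charge` (nC), `baseline_current` (nA), `sensor_id`.
#' @export
integrate_trace <- function(trace, window = 0.1) {
  base <- baseline_current(trace, window)
  sel <- phase_window(trace, "external")
  q <- trapz_strict(trace$time[sel], trace$current[sel] - base)
  structure(list(condition = trace$condition$label,
                 total_charge = q,
                 baseline_current = base,
                 sensor_id = trace$sensor_id),
            class = "ms_charge_measurement")
}

#' Peak transport current of a trace
#'
#' Baseline-subtracted external-phase current, lightly smoothed with a
#' centred moving average, reported at its largest absolute excursion
#' (signed).
#'
#' @inheritParams baseline_current
#' @param smooth_k moving-average width in samples (odd; default 5).
#' @return peak current (nA, signed).
#' @export
peak_current <- function(trace, smooth_k = 5L, window = 0.1) {
  base <- baseline_current(trace, window)
  sel <- phase_window(trace, "external")
  y <- trace$current[sel] - base
  if (smooth_k > 1L) {
    y <- stats::filter(y, rep(1 / smooth_k, smooth_k), sides = 2)
    y <- y[!is.na(y)]
  }
  y[which.max(abs(y))]
}

#' Per-condition charge summary of an SSME experiment
#'
#' @param experiment a `ms_ssme_experiment`, or a plain list of
#'   `ms_ssme_trace` objects.
#' @param window baseline window (s).
#' @return data frame with one row per condition label: `condition`,
#'   `total_charge` (mean over sensors, nC), `sd_charge`, `sem_charge`,
#'   `n_sensors`, `baseline_current`.
#' @export
measure_charges <- function(experiment, window = 0.1) {
  traces <- if (inherits(experiment, "ms_ssme_experiment")) experiment$traces
            else experiment
  meas <- lapply(traces, integrate_trace, window = window)
  lab <- vapply(meas, `[[`, "", "condition")
  q <- vapply(meas, `[[`, 0, "total_charge")
  b <- vapply(meas, `[[`, 0, "baseline_current")
  out <- do.call(rbind, lapply(split(seq_along(q), lab), function(i) {
    data.frame(condition = lab[i[1L]],
               total_charge = mean(q[i]),
               sd_charge = if (length(i) > 1L) stats::sd(q[i]) else 0,
               sem_charge = if (length(i) > 1L)
                 stats::sd(q[i]) / sqrt(length(i)) else 0,
               n_sensors = length(i),
               baseline_current = mean(b[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Michaelis-Menten fit of drug-gated transport
#'
#' Least-squares fit of `v = Imax * c / (Km + c)` to peak currents (or
#' integrated charges) versus drug concentration.  Noiseless model data are
#' recovered to better than 1e-6 relative error.
#'
#' @param concentration drug concentrations (uM), >= 4 values.
#' @param response peak currents (nA) or charges (nC) at each concentration.
#' @return object of class `ms_gating_fit`: `Km` (uM), `Imax`, `se_Km`.
#' @examples
#' conc <- c(0.5, 1, 2, 5, 10, 20, 50)
#' fit_gating(conc, conc / (5 + conc))$Km  # 5
#' @export
fit_gating <- function(concentration, response) {
  if (length(concentration) != length(response) ||
      length(unique(concentration)) < 4L) {
    ms_error("ms_invalid_grid",
             "need >= 4 distinct concentrations with matching responses")
  }
  vmax0 <- max(abs(response))
  km0 <- concentration[which.min(abs(abs(response) - vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ Imax * concentration / (Km + concentration),
                      start = list(Imax = max(response), Km = max(km0, 1e-3)),
                      lower = c(Imax = -Inf, Km = 1e-9)),
    error = function(e) ms_error("ms_fit_failure", paste(
      "gating fit did not converge:", conditionMessage(e))))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  if (max(concentration) < 2 * est[["Km"]]) {
    ms_warn("ms_ill_conditioned",
            "concentrations do not saturate the fitted Km; estimate is weak")
  }
  structure(list(Km = est[["Km"]], Imax = est[["Imax"]],
                 se_Km = unname(se[2L]), fit = fit),
            class = "ms_gating_fit")
}

#' Generate peak-current gating data from the simulator
#'
#' For each concentration simulates `n_sensors` no-gradient traces (drug equal
#' on both faces, the condition used for the saturation analysis), plus a
#' matched no-drug control, and returns control-subtracted peak currents with
#' multiplicative noise at `noise_frac`.
#'
#' @param params a [transporter_params()] (typically the proton-uniport
#'   harmane preset).
#' @param concentrations drug grid (uM).
#' @param n_sensors sensors per concentration.
#' @param noise_frac multiplicative noise fraction on the peak current.
#' @param seed master seed.
#' @return data frame `conc_uM`, `sensor`, `peak_nA`.
#' @export
gen_gating_data <- function(params,
                            concentrations = c(0.5, 1, 2, 5, 10, 20, 35, 50),
                            n_sensors = 3L, noise_frac = 0.05, seed = NULL) {
  if (any(concentrations < 0)) {
    ms_error("ms_invalid_grid", "concentrations must be >= 0")
  }
  rows <- list()
  k <- 0L
  for (conc in concentrations) {
    cond <- gradient_condition("no_gradient", drug_in = conc, drug_out = conc)
    ctrl <- gradient_condition("no_drug")
    peak_true <- steady_state_charge(params, cond) / params$tau
    peak_ctrl <- steady_state_charge(params, ctrl) / params$tau
    for (s in seq_len(n_sensors)) {
      k <- k + 1L
      tr <- simulate_ssme_trace(params, cond, noise_sd = 0,
                                seed = NULL, sensor_id = sprintf("s%d", s))
      pk <- peak_current(tr) - peak_ctrl
      rows[[k]] <- data.frame(conc_uM = conc, sensor = s, peak_nA = pk)
    }
  }
  out <- do.call(rbind, rows)
  with_seed(seed, {
    out$peak_nA <- out$peak_nA * exp(stats::rnorm(nrow(out), 0, noise_frac))
    out
  })
}

#' Classify the transport mode from the four-condition charge pattern
#'
#' Decision rules operate on the drug-induced charges
#' `dQ_c = Q_c - Q_no_drug` for the three drug conditions, with significance
#' threshold `S = k_sig * max(sd_pooled, q_floor)` where `sd_pooled` is the
#' replicate SD pooled over all four conditions and `q_floor` an absolute
#' charge-resolution floor:
#'
#' 1. no drug-induced charge significant: **inactive**;
#' 2. all three significant with signs `(+, +, -)` on (no-gradient,
#'    against-gradient, with-gradient): **antiport**; `(+, -, +)`:
#'    **symport** (coupled transport reverses when the drug gradient flips);
#' 3. no-gradient charge unchanged by drug, gradient charges significant with
#'    opposite signs tracking the drug gradient and the drug charge
#'    (`z_D != 0`): **drug uniport**;
#' 4. all three positive, significant and pairwise equal within `eps_rel`:
#'    **proton uniport** (signal set by the fixed proton gradient alone);
#' 5. otherwise **ambiguous**.
#'
#' @param charges data frame from [measure_charges()] containing the four
#'   standard condition labels.
#' @param drug_charge drug charge `z_D` in elementary charges (default +1).
#' @param k_sig significance multiplier (default 3).
#' @param eps_rel relative equality tolerance for the proton-uniport test
#'   (default 0.2).
#' @param q_floor absolute charge-resolution floor (nC, default 0.01).
#' @param sd_source `"pooled"` (default) or `"no_drug"`: which replicate SD
#'   feeds the significance threshold.
#' @return object of class `ms_mode_call`: `mode` and an `evidence` list
#'   (charges, deltas, threshold); the call is a pure function of these.
#' @export
classify_mode <- function(charges, drug_charge = 1, k_sig = 3, eps_rel = 0.2,
                          q_floor = 0.01, sd_source = c("pooled", "no_drug")) {
  sd_source <- match.arg(sd_source)
  need <- c("no_drug", "no_gradient", "against_proton_gradient",
            "with_proton_gradient")
  if (!all(need %in% charges$condition)) {
    ms_error("ms_input_error", paste(
      "missing conditions:",
      paste(setdiff(need, charges$condition), collapse = ", ")))
  }
  qq <- stats::setNames(charges$total_charge, charges$condition)[need]
  sds <- stats::setNames(charges$sd_charge, charges$condition)[need]
  sd_est <- if (sd_source == "pooled") sqrt(mean(sds^2)) else sds[["no_drug"]]
  S <- k_sig * max(sd_est, q_floor)
  dq <- qq[c("no_gradient", "against_proton_gradient",
             "with_proton_gradient")] - qq[["no_drug"]]
  sig <- abs(dq) > S
  sgn <- sign(dq)
  equal_rel <- function(a, b) abs(a - b) <= eps_rel * max(abs(a), abs(b))
  mode <- if (!any(sig)) {
    "inactive"
  } else if (all(sig) && all(sgn == c(1, 1, -1))) {
    "antiport"
  } else if (all(sig) && all(sgn == c(1, -1, 1))) {
    "symport"
  } else if (!sig[1L] && sig[2L] && sig[3L] && drug_charge != 0 &&
             sgn[2L] == -sign(drug_charge) && sgn[3L] == sign(drug_charge)) {
    # drug gradient is inward under "with", outward under "against"
    "drug_uniport"
  } else if (all(sig) && all(dq > 0) &&
             equal_rel(dq[1L], dq[2L]) && equal_rel(dq[1L], dq[3L]) &&
             equal_rel(dq[2L], dq[3L])) {
    "proton_uniport"
  } else {
    "ambiguous"
  }
  structure(list(mode = mode,
                 evidence = list(charges = charges, deltas = dq,
                                 threshold = S, k_sig = k_sig,
                                 eps_rel = eps_rel, q_floor = q_floor,
                                 sd_source = sd_source,
                                 drug_charge = drug_charge)),
            class = "ms_mode_call")
}

#' @export
print.ms_mode_call <- function(x, ...) {
  cat(sprintf("SSME transport-mode call: %s\n", x$mode))
  d <- x$evidence$deltas
  cat(sprintf("  drug-induced charges (nC): no-gradient %+.3g, against %+.3g, with %+.3g\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  significance threshold: %.3g nC\n", x$evidence$threshold))
  invisible(x)
}

#' Sensor quality control
#'
#' Pass when capacitance lies in the accepted 15--35 nF band and conductance
#' is strictly below 5 nS.
#'
#' @param capacitance_nF sensor capacitance (nF).
#' @param conductance_nS sensor conductance (nS).
#' @return logical (vectorised).
#' @examples
#' sensor_qc(20, 1.5)  # TRUE
#' sensor_qc(35, 5)    # FALSE: conductance bound is strict
#' @export
sensor_qc <- function(capacitance_nF, conductance_nS) {
  capacitance_nF >= 15 & capacitance_nF <= 35 & conductance_nS < 5
}
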