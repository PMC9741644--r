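# independent oracles used to freeze expected values; deliberately written
# with different algorithms than the package code paths they check

# mass-action equilibrium [EH] by damped fixed-point iteration:
# EH = E_T * H_free / (Kd + H_free), H_free = H_add - EH
oracle_occupancy <- function(E_T, H_add, Kd, tol = 1e-12) {
  eh <- 0
  for (i in 1:10000) {
    h_free <- max(H_add - eh, 0)
    eh_new <- E_T * h_free / (Kd + h_free)
    if (abs(eh_new - eh) < tol) return(eh_new)
    eh <- (eh + eh_new) / 2
  }
  eh
}

# hand trapezoid over explicit panels
oracle_trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# exhaustive re-implementation of the differential scoring scheme on a small
# plate set: plain loops, base mean(trim =), sd over supplied control wells
oracle_screen <- function(plate_set, control_wells, trim = 0.10, mult = 2,
                          cutoff = 3) {
  df <- as.data.frame(plate_set)
  keys <- unique(df[, c("compound", "well", "replicate")])
  deltas <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- df[df$compound == k$compound & df$well == k$well &
                df$replicate == k$replicate, ]
    area <- sapply(c("WT", "E14Q"), function(s) {
      ss <- sub[sub$strain == s, ]
      ss <- ss[order(ss$time_h), ]
      oracle_trapz(ss$time_h, ss$signal - ss$signal[1])
    })
    cbind(k, delta = area[["WT"]] - area[["E14Q"]])
  }))
  calls <- NULL
  for (r in unique(deltas$replicate)) {
    sub <- deltas[deltas$replicate == r, ]
    tm <- mean(sub$delta, trim = trim)
    s <- sd(sub$delta[sub$well %in% control_wells])
    sub$call <- ifelse(sub$delta - tm > mult * s, 1L,
                       ifelse(sub$delta - tm < -mult * s, -1L, 0L))
    calls <- rbind(calls, sub)
  }
  out <- aggregate(call ~ compound, calls, sum)
  out$label <- ifelse(out$call >= cutoff, "resistance",
                      ifelse(out$call <= -cutoff, "susceptibility", "none"))
  out
}

# small screen panel used across tests (fast: few timepoints)
make_test_panel <- function(noise_cv = 0.02) {
  c(list(
    screen_preset("hitR", "resistance", effect_size = 0.5,
                  wells_affected = 8L, noise_cv = noise_cv),
    screen_preset("hitS", "susceptibility", effect_size = 0.5,
                  wells_affected = 6L, noise_cv = noise_cv)),
    lapply(sprintf("null-%02d", 1:14), screen_preset, noise_cv = noise_cv))
}

# hand-constructed trace for integration oracles
make_const_trace <- function(i_internal = 0.5, i_external = 2.0,
                             t_int = 0.5, t_ext = 1.0, dt = 0.01,
                             label = "no_gradient") {
  time <- seq(0, 2 * t_int + t_ext, by = dt)
  current <- ifelse(time >= t_int & time <= t_int + t_ext,
                    i_external, i_internal)
  structure(list(
    time = time, current = current,
    phases = data.frame(
      phase = c("internal_1", "external", "internal_2"),
      t_start = c(0, t_int, t_int + t_ext),
      t_end = c(t_int, t_int + t_ext, 2 * t_int + t_ext)),
    condition = gradient_condition(label, drug_in = 8, drug_out = 8),
    sensor_id = "oracle"), class = "ms_ssme_trace")
}
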