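# differential phenotype-microarray scoring:
# paired kinetic curves -> per-well area differentials -> robust hit calls ->
# per-compound resistance/susceptibility scores

#' Scoring configuration for the differential phenotype screen
#'
#' @param trim_fraction fraction trimmed from *each* tail when computing the
#'   trimmed mean of the per-well differentials (default 0.10).
#' @param sd_multiplier a well is a hit when its differential lies strictly
#'   more than `sd_multiplier` non-hit standard deviations from the replicate's
#'   trimmed mean (default 2).
#' @param min_nonhit_wells minimum number of wells used to estimate the
#'   non-hit standard deviation (default 50).
#' @param hit_cutoff compound-level classification cutoff: a summed score
#'   >= `hit_cutoff` is a resistance hit, <= `-hit_cutoff` a susceptibility
#'   hit (default 3).
#' @return a `ms_score_config` list.
#' @export
score_config <- function(trim_fraction = 0.10, sd_multiplier = 2,
                         min_nonhit_wells = 50L, hit_cutoff = 3L) {
  if (!is_scalar_number(trim_fraction) || trim_fraction < 0 ||
      trim_fraction >= 0.5) {
    ms_error("ms_invalid_argument", "trim_fraction must be in [0, 0.5)")
  }
  stopifnot_scalar(sd_multiplier, "sd_multiplier", min = 0, strict = TRUE)
  stopifnot_scalar(min_nonhit_wells, "min_nonhit_wells", min = 1)
  stopifnot_scalar(hit_cutoff, "hit_cutoff", min = 1)
  structure(list(trim_fraction = trim_fraction,
                 sd_multiplier = sd_multiplier,
                 min_nonhit_wells = as.integer(min_nonhit_wells),
                 hit_cutoff = as.integer(hit_cutoff)),
            class = "ms_score_config")
}

#' Area under a kinetic respiration curve
#'
#' Trapezoidal area over the full time window after subtracting the first
#' (t = 0) signal from every point, so a constant curve has zero area and the
#' statistic is invariant to a constant signal offset.
#'
#' @param time_h time grid in hours, strictly increasing, length >= 2.
#' @param signal signal values (arbitrary units).
#' @return area in signal-units x hours.
#' @examples
#' curve_auc(c(0, 1, 2), c(0, 2, 2))  # 3
#' @export
curve_auc <- function(time_h, signal) {
  if (length(time_h) < 2L || anyNA(time_h) || any(diff(time_h) <= 0)) {
    ms_error("ms_invalid_series",
             "time grid must have >= 2 strictly increasing points")
  }
  if (length(signal) != length(time_h)) {
    ms_error("ms_invalid_series", "time and signal lengths differ")
  }
  trapz_strict(time_h, signal - signal[1L])
}

#' Per-well area differentials between paired strains
#'
#' For every (compound, well, replicate) computes the curve areas of the WT
#' and E14Q series and their difference `delta = area_WT - area_E14Q`.
#' Positive values mean the functional transporter helped (resistance
#' direction); negative values mean it hurt (susceptibility direction).
#'
#' @param plate_set a long-format plate set as produced by [gen_plate_set()]
#'   or [read_plate_set()]: columns `compound, well, replicate, strain,
#'   time_h, signal` (plus optionally `plate, conc_rank`).
#' @return data frame with one row per (compound, well, replicate):
#'   `compound, well, conc_rank, replicate, area_wt, area_e14q, delta`.
#' @export
compute_deltas <- function(plate_set) {
  req <- c("compound", "well", "replicate", "strain", "time_h", "signal")
  miss <- setdiff(req, names(plate_set))
  if (length(miss)) {
    ms_error("ms_schema_error",
             paste("plate set missing columns:", paste(miss, collapse = ", ")))
  }
  key <- interaction(plate_set$compound, plate_set$well, plate_set$replicate,
                     drop = TRUE, sep = "\r")
  pieces <- split(seq_len(nrow(plate_set)), key)
  out <- lapply(pieces, function(idx) {
    sub <- plate_set[idx, ]
    wt <- sub[sub$strain == "WT", ]
    eq <- sub[sub$strain == "E14Q", ]
    if (!nrow(wt) || !nrow(eq)) {
      ms_error("ms_pairing_error", sprintf(
        "well '%s' (compound '%s', replicate %s) lacks its %s series",
        sub$well[1L], sub$compound[1L], sub$replicate[1L],
        if (nrow(wt)) "E14Q" else "WT"))
    }
    wt <- wt[order(wt$time_h), ]
    eq <- eq[order(eq$time_h), ]
    if (nrow(wt) != nrow(eq) || any(wt$time_h != eq$time_h)) {
      ms_error("ms_pairing_error", sprintf(
        "well '%s': WT and E14Q time grids differ", sub$well[1L]))
    }
    data.frame(compound = sub$compound[1L],
               well = sub$well[1L],
               conc_rank = if ("conc_rank" %in% names(sub)) sub$conc_rank[1L]
                           else NA_integer_,
               replicate = sub$replicate[1L],
               area_wt = curve_auc(wt$time_h, wt$signal),
               area_e14q = curve_auc(eq$time_h, eq$signal))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$delta <- out$area_wt - out$area_e14q
  out[order(out$replicate, out$compound, out$well), ]
}

#' Trimmed mean
#'
#' Sorts the values, drops `floor(trim_fraction * n)` from each tail and
#' averages the remainder (so small samples with `k = 0` reduce to the plain
#' mean).
#'
#' @param values numeric vector, non-empty.
#' @param trim_fraction per-tail trim fraction in [0, 0.5).
#' @return scalar mean.
#' @examples
#' trimmed_mean(c(1:9, 1000), 0.10)  # 5.5
#' @export
trimmed_mean <- function(values, trim_fraction = 0.10) {
  if (!length(values) || anyNA(values)) {
    ms_error("ms_invalid_argument", "values must be non-empty and NA-free")
  }
  n <- length(values)
  k <- floor(trim_fraction * n)
  s <- sort(values)
  mean(s[(k + 1L):(n - k)])
}

#' Standard deviation of the non-hit wells
#'
#' Estimates the null spread of the per-well differentials within one
#' replicate.  When `nonhit_wells` is supplied (the authoritative path:
#' a character vector of well ids known to carry inactive compounds) the
#' sample SD is taken over those wells.  Otherwise the
#' `config$min_nonhit_wells` wells whose deltas lie closest to the replicate's
#' trimmed mean are selected automatically; note that central selection
#' shrinks the estimate when the pool barely exceeds the minimum, so supply
#' known controls whenever they exist.
#'
#' @param deltas data frame from [compute_deltas()] restricted to one
#'   replicate.
#' @param nonhit_wells optional character vector of well ids (or `NULL` for
#'   auto selection).
#' @param config a [score_config()].
#' @return list with `sd`, the selected `wells`, and the `method` used.
#' @export
nonhit_sd <- function(deltas, nonhit_wells = NULL, config = score_config()) {
  if (!is.null(nonhit_wells)) {
    sel <- deltas$well %in% nonhit_wells
    if (sum(sel) < config$min_nonhit_wells) {
      ms_error("ms_insufficient_controls", sprintf(
        "only %d supplied control wells present; need >= %d",
        sum(sel), config$min_nonhit_wells))
    }
    return(list(sd = stats::sd(deltas$delta[sel]),
                wells = deltas$well[sel], method = "supplied"))
  }
  if (nrow(deltas) < config$min_nonhit_wells) {
    ms_error("ms_insufficient_controls", sprintf(
      "replicate has %d wells; need >= %d for the non-hit SD",
      nrow(deltas), config$min_nonhit_wells))
  }
  tm <- trimmed_mean(deltas$delta, config$trim_fraction)
  ord <- order(abs(deltas$delta - tm))
  keep <- ord[seq_len(config$min_nonhit_wells)]
  list(sd = stats::sd(deltas$delta[keep]),
       wells = deltas$well[keep], method = "auto")
}

#' Call a single well
#'
#' `+1` when `delta - tm` is strictly greater than `sd_multiplier * sd`
#' (resistance), `-1` when strictly less than the negative cutoff
#' (susceptibility), `0` otherwise.  With `sd = 0` any nonzero deviation is a
#' hit.
#'
#' @param delta well differential (area units).
#' @param tm replicate trimmed mean.
#' @param sd replicate non-hit standard deviation (>= 0).
#' @param config a [score_config()].
#' @return integer vector of calls in \{-1, 0, +1\} (vectorised over `delta`).
#' @export
call_well <- function(delta, tm, sd, config = score_config()) {
  if (sd < 0) ms_error("ms_invalid_argument", "sd must be >= 0")
  cut <- config$sd_multiplier * sd
  dev <- delta - tm
  as.integer(ifelse(dev > cut, 1L, ifelse(dev < -cut, -1L, 0L)))
}

#' Sum well calls into a compound score
#'
#' @param well_calls integer calls in \{-1, 0, +1\} pooled across replicates.
#' @param config a [score_config()].
#' @param n_expected expected number of scored wells (default 8); compounds
#'   with fewer observations are scored but flagged `partial` (the cutoff is
#'   absolute, not rescaled).
#' @return list `ms_compound_score`: `score`, `call`
#'   (resistance/susceptibility/none), `well_calls`, `partial`.
#' @export
score_compound <- function(well_calls, config = score_config(),
                           n_expected = 8L) {
  if (!length(well_calls) || !all(well_calls %in% c(-1L, 0L, 1L))) {
    ms_error("ms_invalid_argument", "well_calls must be in {-1, 0, +1}")
  }
  score <- sum(well_calls)
  call <- if (score >= config$hit_cutoff) "resistance"
          else if (score <= -config$hit_cutoff) "susceptibility"
          else "none"
  structure(list(score = as.integer(score), call = call,
                 well_calls = as.integer(well_calls),
                 partial = length(well_calls) < n_expected),
            class = "ms_compound_score")
}

#' Run the full differential screen
#'
#' Pipeline: [curve_auc()] per series, [compute_deltas()], per-replicate
#' [trimmed_mean()] and [nonhit_sd()], [call_well()] per well, and
#' [score_compound()] per compound, pooling calls across replicates.
#' Deterministic for a given plate set.
#'
#' @param plate_set long-format plate set (see [compute_deltas()]).
#' @param config a [score_config()].
#' @param controls optional controls for the non-hit SD: either a character
#'   vector of control *compound* labels, or a character vector of well ids.
#'   Defaults to the plate set's own manifest control compounds when present.
#' @return data frame of class `ms_screen_result`, one row per compound with
#'   `compound, n_wells, score, call, partial`, sorted by score (descending).
#'   Attributes: `replicate_stats` (tm/sd per replicate) and `well_calls`.
#' @examples
#' ps <- gen_plate_set(c(list(screen_preset("MV", "resistance", 0.5, 8)),
#'                       lapply(1:14, function(i) screen_preset(paste0("c", i)))),
#'                     seed = 1)
#' run_screen(ps)[1, ]
#' @export
run_screen <- function(plate_set, config = score_config(), controls = NULL) {
  deltas <- compute_deltas(plate_set)
  manifest <- attr(plate_set, "manifest")
  if (is.null(controls) && !is.null(manifest$control_compounds) &&
      length(manifest$control_compounds)) {
    controls <- manifest$control_compounds
  }
  # map compound-label controls onto well ids
  control_wells <- NULL
  if (!is.null(controls)) {
    control_wells <- if (any(controls %in% deltas$compound)) {
      unique(deltas$well[deltas$compound %in% controls])
    } else {
      controls
    }
  }
  stats_list <- list()
  calls <- vector("list", 0L)
  for (rep_id in sort(unique(deltas$replicate))) {
    sub <- deltas[deltas$replicate == rep_id, ]
    tm <- trimmed_mean(sub$delta, config$trim_fraction)
    nh <- nonhit_sd(sub, control_wells, config)
    sub$call <- call_well(sub$delta, tm, nh$sd, config)
    stats_list[[as.character(rep_id)]] <-
      data.frame(replicate = rep_id, trimmed_mean = tm, nonhit_sd = nh$sd,
                 n_nonhit = length(nh$wells), method = nh$method)
    calls[[length(calls) + 1L]] <- sub
  }
  well_calls <- do.call(rbind, calls)
  scores <- lapply(split(well_calls, well_calls$compound), function(sub) {
    sc <- score_compound(sub$call, config)
    data.frame(compound = sub$compound[1L], n_wells = nrow(sub),
               score = sc$score, call = sc$call, partial = sc$partial)
  })
  out <- do.call(rbind, scores)
  out <- out[order(-out$score, out$compound), ]
  rownames(out) <- NULL
  attr(out, "replicate_stats") <- do.call(rbind, stats_list)
  attr(out, "well_calls") <- well_calls
  attr(out, "config") <- config
  class(out) <- c("ms_screen_result", "data.frame")
  out
}
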