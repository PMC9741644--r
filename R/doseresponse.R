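# growth readouts: relative growth, sigmoid IC50 fits, strain comparison,
# and checkerboard MIC/FIC synergy analysis

#' Relative growth of a dose-response plate
#'
#' Divides each replicate's OD600 by its own zero-drug OD, so
#' `relative_growth(0) = 1` by construction.
#'
#' @param plate data frame with `conc_uM`, `od600` and optionally `replicate`
#'   (assumed a single replicate when absent), e.g. from [gen_growth_plate()].
#' @return the plate with a `relative_growth` column added, class
#'   `ms_dose_response`.
#' @export
relative_growth <- function(plate) {
  if (!all(c("conc_uM", "od600") %in% names(plate))) {
    ms_error("ms_schema_error", "plate needs columns conc_uM and od600")
  }
  if (!"replicate" %in% names(plate)) plate$replicate <- 1L
  out <- lapply(split(plate, plate$replicate), function(sub) {
    ref <- sub$od600[sub$conc_uM == 0]
    if (!length(ref) || !all(is.finite(ref)) || mean(ref) <= 0) {
      ms_error("ms_normalization_error",
               "replicate lacks a positive zero-drug OD600 reference")
    }
    sub$relative_growth <- sub$od600 / mean(ref)
    sub
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ms_dose_response", "data.frame")
  out
}

#' Sigmoid IC50 fit
#'
#' Least-squares fit of `g(c) = top / (1 + (c / ic50)^hill)` (floor fixed at
#' zero, `top` free but capped at 1.2 on the relative-growth scale) to
#' relative growth versus concentration.  Noiseless model data are recovered
#' to better than 1e-6 relative error.
#'
#' @param dr a `ms_dose_response` (from [relative_growth()]), or a data frame
#'   with `conc_uM` and `relative_growth`.
#' @return object of class `ms_ic50_fit`: `ic50` (uM), `hill`, `top`,
#'   `se_ic50`.
#' @examples
#' conc <- c(0, 10, 30, 60, 130, 260, 520)
#' fit_ic50(data.frame(conc_uM = conc,
#'                     relative_growth = 1 / (1 + (conc / 130)^2)))$ic50
#' @export
fit_ic50 <- function(dr) {
  if (!all(c("conc_uM", "relative_growth") %in% names(dr))) {
    ms_error("ms_schema_error",
             "need columns conc_uM and relative_growth (see relative_growth())")
  }
  conc <- dr$conc_uM
  g <- dr$relative_growth
  if (length(unique(conc)) < 5L) {
    ms_error("ms_invalid_grid", "need >= 5 distinct concentrations to fit")
  }
  if (diff(range(g)) < 0.05) {
    ms_error("ms_fit_failure",
             "growth is flat across the grid; no transition to fit")
  }
  top0 <- mean(g[conc == min(conc)])
  ic0 <- conc[conc > 0][which.min(abs(g[conc > 0] - top0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ top / (1 + (conc / ic50)^hill),
                      start = list(top = top0, ic50 = ic0, hill = 1.5),
                      lower = c(top = 0, ic50 = 1e-9, hill = 0.05),
                      upper = c(top = 1.2, ic50 = Inf, hill = 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) ms_error("ms_fit_failure", paste(
      "IC50 fit did not converge:", conditionMessage(e))))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(ic50 = est[["ic50"]], hill = est[["hill"]],
                 top = est[["top"]], se_ic50 = unname(se[2L]), fit = fit),
            class = "ms_ic50_fit")
}

#' Compare IC50 fits of the functional and nonfunctional strains
#'
#' @param fit_wt,fit_e14q `ms_ic50_fit` objects for the WT (functional) and
#'   E14Q (nonfunctional) strains.
#' @param conf_mult CI half-width in standard errors (default 1.96).
#' @return list of class `ms_strain_comparison`: `ic50_wt`, `ic50_e14q`,
#'   `ratio` (WT / E14Q), `percent_lower` = 100 * (E14Q - WT) / E14Q (positive
#'   when the functional transporter sensitises the cells), and
#'   `no_difference` (TRUE when the confidence intervals overlap).
#' @export
compare_strains <- function(fit_wt, fit_e14q, conf_mult = 1.96) {
  iw <- fit_wt$ic50
  ie <- fit_e14q$ic50
  ci_w <- iw + c(-1, 1) * conf_mult * (fit_wt$se_ic50 %||% NA_real_)
  ci_e <- ie + c(-1, 1) * conf_mult * (fit_e14q$se_ic50 %||% NA_real_)
  overlap <- if (anyNA(c(ci_w, ci_e))) NA else ci_w[1L] <= ci_e[2L] &&
    ci_e[1L] <= ci_w[2L]
  structure(list(ic50_wt = iw, ic50_e14q = ie, ratio = iw / ie,
                 percent_lower = 100 * (ie - iw) / ie,
                 no_difference = overlap),
            class = "ms_strain_comparison")
}

#' @export
print.ms_strain_comparison <- function(x, ...) {
  cat(sprintf(
    "IC50 comparison: WT %.4g uM vs E14Q %.4g uM (%.1f%% lower in WT%s)\n",
    x$ic50_wt, x$ic50_e14q, x$percent_lower,
    if (isTRUE(x$no_difference)) "; CIs overlap - no difference" else ""))
  invisible(x)
}

#' Minimum inhibitory concentration along one drug axis
#'
#' The MIC is the smallest tested concentration at which growth is reduced to
#' at most `threshold_frac` of the background *and stays there at every
#' higher tested concentration* (sustained-inhibition rule, which makes
#' "inhibits all growth" operational on noisy plates).  When no concentration
#' qualifies the MIC is censored at "> max tested" and returned as such,
#' never as a number.
#'
#' @param conc monotone increasing concentrations including 0.
#' @param od OD600 (or growth fraction) at each concentration.
#' @param background reference OD; defaults to the zero-drug value.
#' @param threshold_frac growth threshold as a fraction of background
#'   (default 0.10).
#' @return list of class `ms_mic`: `mic` (uM, `NA` when censored),
#'   `censored`, `limit` (max tested).
#' @examples
#' compute_mic(c(0, 1, 2, 4, 8), c(1, 0.8, 0.4, 0.08, 0.01))$mic  # 4
#' @export
compute_mic <- function(conc, od, background = NULL, threshold_frac = 0.10) {
  if (length(conc) != length(od) || length(conc) < 2L ||
      any(diff(conc) <= 0) || conc[1L] != 0) {
    ms_error("ms_invalid_design",
             "conc must be monotone increasing, include 0, and match od")
  }
  background <- background %||% od[1L]
  inhibited <- od <= threshold_frac * background
  sustained <- rev(cumprod(rev(inhibited))) == 1
  idx <- which(sustained & conc > 0)
  if (!length(idx)) {
    return(structure(list(mic = NA_real_, censored = TRUE, limit = max(conc)),
                     class = "ms_mic"))
  }
  structure(list(mic = conc[min(idx)], censored = FALSE, limit = max(conc)),
            class = "ms_mic")
}

#' Fractional inhibitory concentration index
#'
#' The two-drug FIC arithmetic: `FIC_A = MIC_(A+B) / MIC_A`,
#' `FIC_B = MIC_(B+A) / MIC_B`, `FIC = FIC_A + FIC_B`, classified as
#' synergistic (FIC < 0.5), indifferent (0.5 <= FIC < 1, boundary inclusive)
#' or antagonistic (FIC >= 1).
#'
#' @param mic_a,mic_b single-agent MICs.
#' @param mic_a_in_b MIC of drug A in the presence of B.
#' @param mic_b_in_a MIC of drug B in the presence of A.
#' @return list: `fic_a`, `fic_b`, `fic`, `call`.
#' @examples
#' fic_index(8, 4, 1, 1)$fic   # 1/8 + 1/4 = 0.375, synergistic
#' fic_index(8, 4, 8, 4)$fic   # 2, antagonistic
#' @export
fic_index <- function(mic_a, mic_b, mic_a_in_b, mic_b_in_a) {
  fa <- mic_a_in_b / mic_a
  fb <- mic_b_in_a / mic_b
  list(fic_a = fa, fic_b = fb, fic = fa + fb, call = classify_fic(fa + fb))
}

classify_fic <- function(fic) {
  ifelse(fic < 0.5, "synergistic",
         ifelse(fic < 1, "indifferent", "antagonistic"))
}

#' Checkerboard MIC/FIC synergy analysis
#'
#' Computes single-agent MICs from the two zero-partner axes, locates the
#' growth/no-growth interface, and evaluates the FIC index at every interface
#' combination well (both drugs present): a well is on the interface when it
#' is inhibited (growth at most `threshold_frac` of the drug-free background)
#' but its neighbour at the next lower concentration of either drug grows.
#' Each interface well contributes `conc_A / MIC_A + conc_B / MIC_B`; the
#' reported index is the mean, classified as synergistic / indifferent /
#' antagonistic.
#'
#' @param cb a `ms_checkerboard` (from [gen_checkerboard()] or
#'   [read_checkerboard()]).
#' @param threshold_frac growth threshold (default 0.10).
#' @return object of class `ms_fic_result`: `fic` (mean index), `call`,
#'   `mic_a`, `mic_b`, `mic_a_in_b`, `mic_b_in_a` (the lowest combination
#'   MICs), and `interface_wells` (per-well table with fic_a/fic_b/fic).
#' @export
compute_fic <- function(cb, threshold_frac = 0.10) {
  od <- cb$od
  gridA <- cb$gridA
  gridB <- cb$gridB
  background <- od[1L, 1L]
  if (!is.finite(background) || background <= 0) {
    ms_error("ms_normalization_error", "drug-free well has no growth")
  }
  mic_a <- compute_mic(gridA, od[, 1L], background, threshold_frac)
  mic_b <- compute_mic(gridB, od[1L, ], background, threshold_frac)
  if (mic_a$censored || mic_b$censored) {
    ms_error("ms_cannot_normalize", sprintf(
      "censored single-agent MIC (%s): FIC undefined",
      paste(c(cb$compound_a, cb$compound_b)[c(mic_a$censored,
                                              mic_b$censored)],
            collapse = ", ")))
  }
  inhibited <- od <= threshold_frac * background
  wells <- list()
  for (i in 2:length(gridA)) for (j in 2:length(gridB)) {
    if (!inhibited[i, j]) next
    if (!inhibited[i - 1L, j] || !inhibited[i, j - 1L]) {
      f <- fic_index(mic_a$mic, mic_b$mic, gridA[i], gridB[j])
      wells[[length(wells) + 1L]] <- data.frame(
        conc_a = gridA[i], conc_b = gridB[j],
        fic_a = f$fic_a, fic_b = f$fic_b, fic = f$fic)
    }
  }
  if (!length(wells)) {
    ms_error("ms_cannot_normalize",
             "no inhibited combination wells: interface undefined")
  }
  wells <- do.call(rbind, wells)
  fic <- mean(wells$fic)
  structure(list(fic = fic, call = classify_fic(fic),
                 mic_a = mic_a$mic, mic_b = mic_b$mic,
                 mic_a_in_b = min(wells$conc_a),
                 mic_b_in_a = min(wells$conc_b),
                 interface_wells = wells,
                 threshold_frac = threshold_frac),
            class = "ms_fic_result")
}

#' @export
print.ms_fic_result <- function(x, ...) {
  cat(sprintf(
    "Checkerboard FIC analysis\n  MIC A = %.4g uM, MIC B = %.4g uM\n  mean FIC index = %.3g over %d interface wells -> %s\n",
    x$mic_a, x$mic_b, x$fic, nrow(x$interface_wells), x$call))
  invisible(x)
}
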