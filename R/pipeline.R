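# orchestration: seeded, config-driven runs over the packaged generators and
# analysis stages, with provenance recorded in the run report

#' Default pipeline configuration
#'
#' A run executes any subset of the five stages, each fed either by a packaged
#' preset (generated on the fly) or by input files in the documented schemas.
#'
#' @param stages character vector among `"screen"`, `"binding"`, `"ssme"`,
#'   `"growth"`, `"checkerboard"`.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir output directory, or `NULL` to skip writing artifacts.
#' @param screen,binding,ssme,growth,checkerboard per-stage option lists
#'   (`preset` name or `path`/`paths`, plus stage parameters).
#' @return a `ms_run_config` list.
#' @export
run_config <- function(stages = c("screen", "binding", "ssme", "growth",
                                  "checkerboard"),
                       seed = 1L, out_dir = NULL,
                       screen = list(preset = "mv_screen"),
                       binding = list(preset = "harmane_binding"),
                       ssme = list(preset = "harmane_proton_uniport"),
                       growth = list(preset = "harmane_growth"),
                       checkerboard = list(preset = "kanamycin_harmane")) {
  structure(list(stages = stages, seed = seed, out_dir = out_dir,
                 screen = screen, binding = binding, ssme = ssme,
                 growth = growth, checkerboard = checkerboard),
            class = "ms_run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path config file path.
#' @return a `ms_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_error <- function(stage, e) {
  ms_error("ms_stage_error",
           sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           stage = stage)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (generate or load inputs, then
#' score / fit / classify), optionally writes the tabular and JSON artifacts
#' to `config$out_dir`, and returns a run report carrying every numeric
#' result, the thresholds and seeds used, and a config hash for provenance.
#' Re-running with an identical config reproduces identical numbers.
#'
#' @param config a [run_config()] (or path to a YAML/JSON config).
#' @return list of class `ms_run_report` with elements `results` (per-stage),
#'   `provenance` (config, hash, package version, timestamp), `warnings`.
#' @examples
#' rep <- run_pipeline(run_config(stages = c("binding", "checkerboard")))
#' rep$results$checkerboard$fic
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  results <- list()
  warns <- character(0)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }

  for (stage in config$stages) {
    opts <- config[[stage]] %||% list()
    seed <- opts$seed %||% derive_seed(config$seed,
                                       match(stage, config$stages))
    res <- tryCatch(switch(stage,
      screen = {
        ps <- if (!is.null(opts$path)) read_plate_set(opts$path)
              else generate_preset(opts$preset %||% "mv_screen", seed = seed)
        scores <- run_screen(ps, config = opts$config %||% score_config(),
                             controls = opts$controls)
        emit("screen_scores.tsv", function(f)
          utils::write.table(as.data.frame(scores), f, sep = "\t",
                             row.names = FALSE, quote = FALSE))
        scores
      },
      binding = {
        tt <- if (!is.null(opts$path)) read_titration(opts$path,
                                                      opts$E_T %||% 10)
              else generate_preset(opts$preset %||% "harmane_binding",
                                   seed = seed)
        fit <- fit_titration(tt)
        emit("binding_fit.json", function(f)
          jsonlite::write_json(fit[c("Kd", "se_Kd", "F_EH", "F_E",
                                     "residual_sse")],
                               f, auto_unbox = TRUE, digits = NA))
        fit
      },
      ssme = {
        charges <- if (!is.null(opts$paths)) {
          measure_charges(lapply(opts$paths, read_ssme_trace))
        } else {
          params <- generate_preset(opts$preset %||% "harmane_proton_uniport")
          measure_charges(simulate_ssme_experiment(params, seed = seed))
        }
        call <- classify_mode(charges,
                              drug_charge = opts$drug_charge %||% 1)
        emit("ssme_charges.tsv", function(f)
          utils::write.table(charges, f, sep = "\t", row.names = FALSE,
                             quote = FALSE))
        emit("ssme_mode.json", function(f)
          jsonlite::write_json(list(mode = call$mode,
                                    threshold_nC = call$evidence$threshold,
                                    deltas_nC = as.list(call$evidence$deltas)),
                               f, auto_unbox = TRUE, digits = NA))
        call
      },
      growth = {
        pair <- if (!is.null(opts$paths)) {
          lapply(opts$paths, read_dose_response)
        } else {
          generate_preset(opts$preset %||% "harmane_growth", seed = seed)
        }
        fits <- lapply(pair, function(p) fit_ic50(relative_growth(p)))
        cmp <- compare_strains(fits[[1L]], fits[[2L]])
        emit("ic50.tsv", function(f)
          utils::write.table(
            data.frame(strain = names(fits),
                       ic50_uM = vapply(fits, `[[`, 0, "ic50"),
                       hill = vapply(fits, `[[`, 0, "hill")),
            f, sep = "\t", row.names = FALSE, quote = FALSE))
        list(fits = fits, comparison = cmp)
      },
      checkerboard = {
        cb <- if (!is.null(opts$path)) read_checkerboard(opts$path)
              else generate_preset(opts$preset %||% "kanamycin_harmane",
                                   seed = seed)
        fic <- compute_fic(cb, opts$threshold_frac %||% 0.10)
        emit("fic.json", function(f)
          jsonlite::write_json(fic[c("fic", "call", "mic_a", "mic_b",
                                     "mic_a_in_b", "mic_b_in_a")],
                               f, auto_unbox = TRUE, digits = NA))
        fic
      },
      ms_error("ms_stage_error", sprintf("unknown stage '%s'", stage))),
      error = function(e) {
        if (inherits(e, "ms_stage_error")) stop(e)
        stage_error(stage, e)
      })
    results[[stage]] <- res
  }
  report <- structure(list(
    results = results,
    provenance = list(config = config,
                      config_hash = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("modeswitch")),
                      seed = config$seed),
    warnings = warns),
    class = "ms_run_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(config_hash = report$provenance$config_hash,
                              package_version =
                                report$provenance$package_version,
                              stages = config$stages,
                              seed = config$seed),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.ms_run_report <- function(x, ...) {
  cat(sprintf("modeswitch run (%s), stages: %s\n",
              x$provenance$config_hash,
              paste(names(x$results), collapse = ", ")))
  invisible(x)
}
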