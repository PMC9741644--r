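# readers/writers for the documented plain-text schemas, plus input validation

#' Read/write a long-format screen plate set
#'
#' CSV columns: `plate,well,compound,conc_rank,replicate,strain,time_h,signal`.
#'
#' @param path CSV file path.
#' @return `read_plate_set()`: a `ms_plate_set` data frame.
#' @export
read_plate_set <- function(path) {
  check_file(path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- validate_table(df, schema_columns("screen_curves"), path)
  class(df) <- c("ms_plate_set", "data.frame")
  df
}

#' @rdname read_plate_set
#' @param plate_set a `ms_plate_set`.
#' @export
write_plate_set <- function(plate_set, path) {
  utils::write.csv(as.data.frame(plate_set), path, row.names = FALSE)
  invisible(path)
}

#' Read/write a fluorescence titration
#'
#' CSV columns: `conc_uM,fluorescence[,replicate]`.
#'
#' @param path CSV file path.
#' @param E_T total dimer concentration (uM) to attach (default 10).
#' @export
read_titration <- function(path, E_T = 10) {
  check_file(path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema_columns("titration"), path)
  attr(df, "E_T") <- E_T
  class(df) <- c("ms_binding_titration", "data.frame")
  df
}

#' @rdname read_titration
#' @param titration a `ms_binding_titration`.
#' @export
write_titration <- function(titration, path) {
  utils::write.csv(as.data.frame(titration), path, row.names = FALSE)
  invisible(path)
}

#' Read/write an SSME trace with its JSON sidecar
#'
#' Trace CSV columns `time_s,current_nA`; the sidecar (same path with
#' extension `.json`) records `sensor_id`, the phase windows, and the gradient
#' condition (`label, pH_in, pH_out, drug_in_uM, drug_out_uM, drug_charge`).
#'
#' @param path trace CSV path.
#' @export
read_ssme_trace <- function(path) {
  check_file(path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) {
    ms_error("ms_schema_error",
             sprintf("trace '%s' lacks its JSON phase sidecar", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema_columns("ssme_trace"), path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("phases", "condition")) {
    if (is.null(meta[[f]])) {
      ms_error("ms_schema_error",
               sprintf("sidecar '%s' lacks field '%s'", sidecar, f))
    }
  }
  cond <- gradient_condition(meta$condition$label,
                             pH_in = meta$condition$pH_in,
                             pH_out = meta$condition$pH_out,
                             drug_in = meta$condition$drug_in_uM,
                             drug_out = meta$condition$drug_out_uM)
  structure(list(time = df$time_s, current = df$current_nA,
                 phases = as.data.frame(meta$phases),
                 condition = cond,
                 sensor_id = meta$sensor_id %||% "sensor-1",
                 drug_charge = meta$condition$drug_charge %||% 1),
            class = "ms_ssme_trace")
}

#' @rdname read_ssme_trace
#' @param trace a `ms_ssme_trace`.
#' @param drug_charge drug charge recorded in the sidecar (default +1).
#' @export
write_ssme_trace <- function(trace, path, drug_charge = 1) {
  utils::write.csv(data.frame(time_s = trace$time,
                              current_nA = trace$current),
                   path, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(
    sensor_id = trace$sensor_id,
    phases = trace$phases,
    condition = list(label = trace$condition$label,
                     pH_in = trace$condition$pH_in,
                     pH_out = trace$condition$pH_out,
                     drug_in_uM = trace$condition$drug_in,
                     drug_out_uM = trace$condition$drug_out,
                     drug_charge = drug_charge)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write a checkerboard OD grid
#'
#' CSV layout: header row carries the drug A concentrations, first column the
#' drug B concentrations, cells the OD600.
#'
#' @param path CSV file path.
#' @param compound_a,compound_b compound labels.
#' @export
read_checkerboard <- function(path, compound_a = "drugA",
                              compound_b = "drugB") {
  check_file(path)
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  gridA <- suppressWarnings(as.numeric(colnames(m)))
  gridB <- suppressWarnings(as.numeric(rownames(m)))
  if (anyNA(gridA) || anyNA(gridB)) {
    ms_error("ms_schema_error",
             "checkerboard header/first column must be numeric concentrations")
  }
  if (gridA[1L] != 0 || gridB[1L] != 0) {
    ms_error("ms_invalid_design",
             "checkerboard lacks a zero-drug row/column (MIC reference undefined)")
  }
  structure(list(gridA = gridA, gridB = gridB,
                 od = t(m), replicates = list(t(m)),
                 compound_a = compound_a, compound_b = compound_b,
                 truth = NULL),
            class = "ms_checkerboard")
}

#' @rdname read_checkerboard
#' @param cb a `ms_checkerboard`.
#' @export
write_checkerboard <- function(cb, path) {
  m <- t(cb$od)
  df <- data.frame(B = cb$gridB, m, check.names = FALSE)
  colnames(df) <- c(sprintf("%s_uM", cb$compound_b), cb$gridA)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response table
#'
#' CSV columns: `conc_uM,od600[,replicate][,strain][,condition]`.
#'
#' @param path CSV file path.
#' @export
read_dose_response <- function(path) {
  check_file(path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema_columns("dose_response"), path)
  df
}

schema_columns <- function(schema) {
  switch(schema,
    screen_curves = c("plate", "well", "compound", "conc_rank", "replicate",
                      "strain", "time_h", "signal"),
    titration = c("conc_uM", "fluorescence"),
    ssme_trace = c("time_s", "current_nA"),
    dose_response = c("conc_uM", "od600"),
    checkerboard = character(0),
    ms_error("ms_schema_error", sprintf("unknown schema '%s'", schema)))
}

check_file <- function(path) {
  if (!file.exists(path)) {
    ms_error("ms_schema_error", sprintf("file '%s' does not exist", path))
  }
  invisible(path)
}

validate_table <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    ms_error("ms_schema_error", sprintf(
      "%s: missing columns %s", path, paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Validate an input file against a documented schema
#'
#' Pre-flight checks run before analysis: column presence, numeric ranges,
#' monotone grids, phase sidecars.  Problems are split into hard `errors`
#' (the file cannot be analysed) and `warnings` (suspicious but usable).
#'
#' @param path file path.
#' @param schema one of `"screen_curves"`, `"titration"`, `"ssme_trace"`,
#'   `"checkerboard"`, `"dose_response"`.
#' @return list of class `ms_validation`: `valid` (logical), `errors`,
#'   `warnings`.
#' @export
validate_inputs <- function(path, schema = c("screen_curves", "titration",
                                             "ssme_trace", "checkerboard",
                                             "dose_response")) {
  schema <- match.arg(schema)
  errors <- character(0)
  warnings <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  if (!file.exists(path)) {
    note(sprintf("file '%s' does not exist", path))
  } else {
    obj <- tryCatch(switch(schema,
                           screen_curves = read_plate_set(path),
                           titration = read_titration(path),
                           ssme_trace = read_ssme_trace(path),
                           checkerboard = read_checkerboard(path),
                           dose_response = read_dose_response(path)),
                    error = function(e) {
                      note(conditionMessage(e))
                      NULL
                    })
    if (!is.null(obj)) {
      if (schema == "screen_curves") {
        tab <- table(obj$compound[!duplicated(paste(obj$compound, obj$well,
                                                    obj$replicate))])
        if (any(tab != 8)) {
          warnings <- c(warnings, sprintf(
            "%d compound(s) do not map to exactly 8 wells (partial design)",
            sum(tab != 8)))
        }
      }
      if (schema == "titration" && any(obj$conc_uM < 0)) {
        note("negative ligand concentrations")
      }
      if (schema == "dose_response" && !any(obj$conc_uM == 0)) {
        note("no zero-drug reference wells")
      }
      if (schema == "ssme_trace" && any(diff(obj$time) <= 0)) {
        note("time grid is not strictly increasing")
      }
    }
  }
  structure(list(valid = !length(errors), errors = errors,
                 warnings = warnings, path = path, schema = schema),
            class = "ms_validation")
}

#' @export
print.ms_validation <- function(x, ...) {
  cat(sprintf("%s [%s]: %s\n", x$path, x$schema,
              if (x$valid) "OK" else "INVALID"))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
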