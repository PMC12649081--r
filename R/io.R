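#' Write a concentration table to CSV with explicit censoring
#'
#' Below-LOQ records are written with an empty value column and the string
#' `"BLQ"` in the dedicated flag column — never as zeros — so censoring
#' stays explicit in the file.
#'
#' @param data Tibble with `subject_id`, `time_h`, `conc_ng_ml`, `blq`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_conc_csv <- function(data, path) {
  stopifnot(all(c("subject_id", "time_h", "conc_ng_ml", "blq") %in% names(data)))
  out <- data |>
    dplyr::mutate(blq = ifelse(.data$blq, "BLQ", ""))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a long-format concentration CSV
#'
#' Accepts the schema written by [write_conc_csv()]: columns `subject_id`,
#' `time_h`, `conc_ng_ml`, `blq` (flag column holding `"BLQ"` for censored
#' records, or a logical). Censored records come back with `blq = TRUE` and
#' `NA` concentration.
#'
#' @param path CSV path.
#' @return A tibble with `subject_id`, `time_h`, `conc_ng_ml`, `blq`.
#' @export
read_conc_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           time_h = readr::col_double(),
                           conc_ng_ml = readr::col_double(),
                           .default = readr::col_character()
                         ))
  req <- c("subject_id", "time_h", "conc_ng_ml")
  if (!all(req %in% names(out)) || nrow(out) == 0L) {
    stop("expected a non-empty CSV with columns ",
         paste(c(req, "blq"), collapse = ", "), call. = FALSE)
  }
  if (!"blq" %in% names(out)) out$blq <- ""
  out$blq <- out$blq %in% c("BLQ", "TRUE", "true") | is.na(out$conc_ng_ml)
  out$conc_ng_ml[out$blq] <- NA_real_
  out
}

#' Write a study configuration to YAML
#'
#' @param config A [study_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$pop <- list(
    tv = unclass(x$pop$tv),
    omega2 = as.list(x$pop$omega2),
    stdev0 = x$pop$stdev0
  )
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Unknown keys are rejected by name so that typos in a configuration file
#' fail loudly rather than silently falling back to defaults.
#'
#' @param path YAML path written by [write_config()] (or hand-authored with
#'   the same keys).
#' @return A [study_config()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("n_horses", "dose_mg", "bw_mean_kg", "bw_sd_kg", "sample_bw",
             "pop", "plasma_schedule_h", "urine_schedule_h", "plasma_loq",
             "urine_loq", "cortisol_baseline_mean", "cortisol_baseline_sd",
             "cortisol_nadir_time_h", "seed")
  bad <- setdiff(names(x), known)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(x$pop)) {
    x$pop <- population_model(
      tv = do.call(pk_params, x$pop$tv),
      omega2 = unlist(x$pop$omega2),
      stdev0 = x$pop$stdev0
    )
  }
  do.call(study_config, x)
}

#' Build a run manifest
#'
#' Records what produced a set of outputs: the command label, the full
#' configuration snapshot, the seed, md5 digests of input/output files, a
#' timestamp and the package version. Reruns with identical inputs and seed
#' reproduce identical digests for deterministic commands.
#'
#' @param command Command label (e.g. `"simulate"`).
#' @param config A [study_config()] snapshot (or `NULL`).
#' @param seed Integer seed used.
#' @param inputs,outputs Named character vectors of file paths.
#' @return A named list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = NULL, seed = NULL,
                         inputs = character(), outputs = character()) {
  digest <- function(paths) {
    if (length(paths) == 0L) return(NULL)
    as.list(tools::md5sum(unname(unlist(paths))))
  }
  cfg <- if (!is.null(config)) {
    x <- unclass(config)
    x$pop <- list(tv = unclass(x$pop$tv), omega2 = as.list(x$pop$omega2),
                  stdev0 = x$pop$stdev0)
    x
  }
  structure(
    list(command = command, config = cfg, seed = seed,
         inputs = digest(inputs), outputs = digest(outputs),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         package_version = as.character(utils::packageVersion("isoflupk"))),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}
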