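## Declarative pipeline runner: chains simulate-*/analyze-* stages from a
## config list (or YAML/JSON file), writes results plus a manifest with
## seeds, versions and checksums so a run is reproducible from its record.

.stage_types <- c("simulate_vesicle", "simulate_contours", "simulate_wave",
                  "analyze_structure", "analyze_spha", "analyze_flicker",
                  "analyze_wave")

## Validate a pipeline config before any stage runs.
.validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$stages) || length(config$stages) == 0) {
    abort("pipeline config must be a list with a non-empty `stages` list")
  }
  ids <- character(0)
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$type) || !st$type %in% .stage_types) {
      abort(paste0("stage ", i, ": unknown or missing type (must be one of ",
                   paste(.stage_types, collapse = ", "), ")"))
    }
    id <- st$id %||% paste0("stage", i)
    if (id %in% ids) abort(paste0("duplicate stage id: ", id))
    ids <- c(ids, id)
    if (grepl("^analyze", st$type)) {
      if (is.null(st$input)) abort(paste0("stage ", id, ": analyze stages need `input`"))
      if (!st$input %in% ids && !file.exists(st$input)) {
        abort(paste0("stage ", id, ": input '", st$input,
                     "' is neither an upstream stage id nor an existing file"))
      }
    }
  }
  config
}

#' Run a declarative simulate/analyze pipeline
#'
#' Executes a chain of stages declared in a config list or YAML/JSON file.
#' Each stage is a list with `type` (one of `simulate_vesicle`,
#' `simulate_contours`, `simulate_wave`, `analyze_structure`,
#' `analyze_spha`, `analyze_flicker`, `analyze_wave`), an optional `id`,
#' `params` passed to the corresponding generator/estimator, and for
#' analyze stages an `input` naming an upstream stage id or a trajectory
#' CSV path. The config is validated in full before any stage runs. A
#' manifest (config, seed, package version, output checksums) is written
#' alongside the outputs; estimates are serialised to JSON with 17
#' significant digits so that write/read round-trips exactly.
#'
#' @param config List, or path to a YAML/JSON file.
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed applied to simulate stages that do not set one.
#' @return Invisibly, a named list of in-memory stage results; the manifest
#'   is at `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("vesimech_run_"),
                         seed = 1) {
  config <- .validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character(0)
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    id <- st$id %||% paste0("stage", i)
    params <- st$params %||% list()
    if (grepl("^simulate", st$type) && is.null(params$seed)) params$seed <- seed
    res <- switch(st$type,
      simulate_vesicle = gen_vesicle_ensemble(do.call(vesicle_config, params)),
      simulate_contours = gen_contour_series(do.call(contour_config, params)),
      simulate_wave = gen_wave_trajectory(do.call(wave_config, params)),
      analyze_structure = membrane_thickness(.pipeline_input(st$input, results)),
      analyze_spha = do.call(spha_kappa,
                             c(list(.pipeline_input(st$input, results)),
                               params)),
      analyze_flicker = do.call(flicker_kappa,
                                c(list(.pipeline_input(st$input, results)),
                                  params)),
      analyze_wave = do.call(amplitude_evolution,
                             c(list(.pipeline_input(st$input, results)),
                               params))
    )
    results[[id]] <- res
    f <- .write_stage_output(res, id, out_dir)
    outputs <- c(outputs, f)
  }
  manifest <- list(
    package = "vesimech",
    version = as.character(utils::packageVersion("vesimech")),
    seed = seed,
    config = config,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

.pipeline_input <- function(input, results) {
  if (input %in% names(results)) return(results[[input]])
  read_trajectory(input)
}

## Serialise one stage result; floats carry 17 significant digits.
.write_stage_output <- function(res, id, out_dir) {
  f <- file.path(out_dir, paste0(id, if (is.data.frame(res)) ".csv" else ".json"))
  if (is.data.frame(res)) {
    readr::write_csv(res, f, progress = FALSE)
  } else if (inherits(res, "contour_series")) {
    f <- file.path(out_dir, paste0(id, ".csv"))
    readr::write_csv(as_tibble(res), f, progress = FALSE)
  } else {
    payload <- if (inherits(res, c("helfrich_fit", "flicker_estimate",
                                   "structural_result"))) {
      as.list(glance(res))
    } else if (inherits(res, "wave_series")) {
      list(amplitude = res$amplitude, extrema = res$extrema)
    } else if (is.list(res) && !is.null(res$AVB)) {
      list(AVB = as.list(glance(res$AVB)), SA = as.list(glance(res$SA)))
    } else {
      list(summary = "unserialised stage result")
    }
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = 17,
                         dataframe = "columns")
  }
  f
}
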