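# Structured run-configuration files (YAML or JSON).

#' Read / write a run configuration file
#'
#' A run configuration is a two-block document — `environment` with the
#' [environment_spec()] fields (`side_length`, `mode`, `n_patches`,
#' `patch_radius`, `items_per_patch_cell`, `uniform_density`, `day_length`,
#' `year_days`, `max_detect_distance`) and `simulation` with the
#' [sim_config()] constants (`e_birth`, `e_max`, `energy_per_item`,
#' `metabolism`, `death_rate`, `max_age_years`, `rescue_floor`, `reach`,
#' `approach_stop`, `detect_max`, `detect_rate`, `eat_time`, `mtf_time`,
#' `speed_cap`, `mutation_rate`) — plus an optional top-level `years`.
#' Omitted keys take the package defaults. The format is chosen by
#' extension: `.yml`/`.yaml` (needs the yaml package) or `.json` (needs
#' jsonlite).
#'
#' @param path file path.
#' @return `read_run_config()` returns a list with `env`
#'   (an [environment_spec()]), `config` (a [sim_config()]) and `years`.
#' @export
read_run_config <- function(path) {
  raw <- read_structured(path)
  envargs <- raw$environment %||% list()
  env <- do.call(environment_spec, envargs)
  simargs <- raw$simulation %||% list()
  mut_rate <- simargs$mutation_rate
  simargs$mutation_rate <- NULL
  if (is.null(simargs$year_length)) simargs$year_length <- env$year_length
  if (!is.null(mut_rate)) simargs$mutation <- mutation_spec(rate = mut_rate)
  cfg <- do.call(sim_config, simargs)
  list(env = env, config = cfg, years = raw$years %||% NULL)
}

#' @rdname read_run_config
#' @param env an [environment_spec()].
#' @param config a [sim_config()].
#' @param years optional run length (years).
#' @export
write_run_config <- function(env, config, path, years = NULL) {
  doc <- list(
    environment = env[c("side_length", "mode", "n_patches", "patch_radius",
                        "items_per_patch_cell", "uniform_density",
                        "day_length", "year_days", "max_detect_distance")],
    simulation = list(
      e_birth = config$e_birth, e_max = config$e_max,
      energy_per_item = config$energy_per_item,
      metabolism = config$metabolism, death_rate = config$death_rate,
      max_age_years = config$max_age_years,
      rescue_floor = config$rescue_floor, reach = config$reach,
      approach_stop = config$approach_stop, detect_max = config$detect_max,
      detect_rate = config$detect_rate, eat_time = config$eat_time,
      mtf_time = config$mtf_time, speed_cap = config$speed_cap,
      mutation_rate = config$mutation$rate))
  if (!is.null(years)) doc$years <- years
  write_structured(doc, path)
  invisible(path)
}

read_structured <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs needs the 'jsonlite' package")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unrecognized config extension (use .yaml, .yml or .json): ", path)
  }
}

write_structured <- function(doc, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML configs needs the 'yaml' package")
    yaml::write_yaml(doc, path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing JSON configs needs the 'jsonlite' package")
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unrecognized config extension (use .yaml, .yml or .json): ", path)
  }
}
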