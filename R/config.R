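#' Composite run configuration
#'
#' Bundles an [obs_spec], a [train_config], a [loc_config] and a
#' [phantom_config] plus file paths into one validated object, the unit
#' the command-line interface consumes and the run manifest records.
#'
#' @param observation,training,localization,phantom Section objects (or
#'   NULL for defaults).
#' @param paths Named list of file paths.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(observation = obs_spec(), training = train_config(),
                       localization = loc_config(), phantom = phantom_config(),
                       paths = list()) {
  stopifnot(inherits(observation, "obs_spec"), inherits(training, "train_config"),
            inherits(localization, "loc_config"),
            inherits(phantom, "phantom_config"), is.list(paths))
  structure(list(observation = observation, training = training,
                 localization = localization, phantom = phantom, paths = paths),
            class = "run_config")
}

config_sections <- function() list(
  observation = obs_spec,
  training = train_config,
  localization = loc_config,
  phantom = phantom_config)

#' Parse a YAML/JSON run configuration
#'
#' Reads a config file with (all-optional) sections `observation`,
#' `training`, `localization`, `phantom` and `paths`. Unknown keys --
#' top-level or within a section -- are rejected with a message naming the
#' key; every omitted field takes its documented default, so an empty file
#' yields the full default configuration (N = 32, H = 3, gamma = 0.9,
#' batch 48, replay 1.5e5, 1500 steps, rho = 3, ...).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config].
#' @export
parse_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  raw <- if (grepl("\\.json$", tolower(path))) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  check_named_list(raw, c(names(config_sections()), "paths"), "config")
  args <- list()
  for (sec in names(config_sections())) {
    ctor <- config_sections()[[sec]]
    fields <- raw[[sec]] %||% list()
    check_named_list(fields, names(formals(ctor)), sec)
    args[[sec]] <- tryCatch(do.call(ctor, fields), error = function(e)
      stop(sprintf("config section '%s': %s", sec, conditionMessage(e)),
           call. = FALSE))
  }
  args$paths <- raw$paths %||% list()
  do.call(run_config, args)
}

config_as_list <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- lapply(cfg[names(config_sections())], unclass)
  out$paths <- cfg$paths
  out
}

#' @rdname parse_config
#' @param cfg A [run_config].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_as_list(cfg), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the fully resolved
#' configuration (defaults filled in), the root seed, the package version,
#' and any extra fields the caller supplies.
#'
#' @param cfg A [run_config].
#' @param path Output JSON path.
#' @param extra Named list of additional fields.
#' @export
run_manifest <- function(cfg, path, extra = list()) {
  obj <- c(list(tool = "qlandmark",
                version = as.character(utils::packageVersion("qlandmark")),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = config_as_list(cfg)),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
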