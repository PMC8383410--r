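# Configuration and result serialisation. Configs are flat key-value maps
# (JSON or YAML by extension) whose keys are exactly the parameter field
# names, optionally plus initial_state, t_span and a solver block; unknown
# keys are an error so typos in sweep specs are caught.

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext == "json") "json"
  else stop("config file must end in .json, .yaml or .yml", call. = FALSE)
}

#' Read a model configuration
#'
#' @param path JSON or YAML file with flat keys matching the
#'   `dormprey_params` fields, plus optional `initial_state` (length-4
#'   array), `t_span` (length-2 array) and `solver` block
#'   (`rtol`, `atol`, `method`, `output_dt`).
#' @return List with `params`, `initial`, `t_span`, `settings` (the last
#'   three `NULL` if absent from the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- switch(config_format(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = yaml::read_yaml(path))
  if (!is.list(raw) || length(raw) == 0 || is.null(names(raw)))
    stop("config must be a non-empty mapping of named keys", call. = FALSE)
  extra <- c("initial_state", "t_span", "solver")
  unknown <- setdiff(names(raw), c(PARAM_NAMES, extra))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- validate_params(as_dormprey_params(raw[intersect(names(raw), PARAM_NAMES)]))
  initial <- if (!is.null(raw$initial_state)) validate_state(unlist(raw$initial_state))
  t_span <- if (!is.null(raw$t_span)) {
    ts <- as.numeric(unlist(raw$t_span))
    if (length(ts) != 2 || ts[2] <= ts[1])
      stop("t_span must be (start, end) with end > start", call. = FALSE)
    ts
  }
  settings <- if (!is.null(raw$solver)) {
    sv <- raw$solver
    bad <- setdiff(names(sv), c("rtol", "atol", "method", "output_dt"))
    if (length(bad))
      stop("unknown solver key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    do.call(solver_settings, sv)
  }
  list(params = params, initial = initial, t_span = t_span,
       settings = settings)
}

#' Write a model configuration
#'
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @param params A `dormprey_params`.
#' @param initial,t_span,settings Optional extras recorded alongside the
#'   parameters.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, params, initial = NULL, t_span = NULL,
                         settings = NULL) {
  params <- validate_params(params)
  cfg <- as.list(params)
  if (!is.null(initial)) cfg$initial_state <- unname(validate_state(initial))
  if (!is.null(t_span)) cfg$t_span <- as.numeric(t_span)
  if (!is.null(settings)) cfg$solver <- unclass(settings)
  switch(config_format(path),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                                     pretty = TRUE),
         yaml = yaml::write_yaml(cfg, path, precision = 17))
  invisible(path)
}

# md5 of the canonical parameter JSON; identifies a run in provenance logs.
params_hash <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(as.list(validate_params(params)),
                              auto_unbox = TRUE, digits = 17), tmp)
  unname(tools::md5sum(tmp))
}

provenance <- function(trajectory) {
  params <- attr(trajectory, "params")
  settings <- attr(trajectory, "settings")
  stats <- attr(trajectory, "solver_stats")
  list(
    package = "dormprey",
    version = as.character(utils::packageVersion("dormprey")),
    params = as.list(params),
    params_hash = params_hash(params),
    initial_state = unname(attr(trajectory, "initial")),
    t_span = attr(trajectory, "t_span"),
    solver = unclass(settings),
    solver_stats = if (!is.null(stats)) as.list(stats)
  )
}

#' Export a trajectory to CSV with a provenance sidecar
#'
#' Writes a tidy CSV (`time, p, y1, y2, z`; comma-separated, header row,
#' full double precision) and a JSON sidecar (`<path>.json`) recording the
#' parameters (17 significant digits), initial state, time span, solver
#' settings and step statistics, so any figure or metric can be regenerated
#' from the sidecar alone.
#'
#' @param trajectory A `dormprey_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  utils::write.csv(format(df, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(provenance(trajectory), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = 17, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores the data frame and, when the JSON sidecar is present, the
#' `params`, `settings`, `initial` and `t_span` attributes.
#'
#' @param path CSV path.
#' @return A `dormprey_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!("time" %in% names(df)) || nrow(df) < 2)
    stop("not a trajectory CSV (needs a 'time' column and >= 2 rows)",
         call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    prov <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(df, "params") <- validate_params(as_dormprey_params(prov$params))
    attr(df, "settings") <- do.call(solver_settings, as.list(prov$solver))
    if (!is.null(prov$initial_state))
      attr(df, "initial") <- validate_state(unlist(prov$initial_state))
    attr(df, "t_span") <- prov$t_span
  }
  class(df) <- c("dormprey_trajectory", "data.frame")
  df
}

#' Export a sweep grid
#'
#' Long-format CSV (`axis1_value, axis2_value, winner, pa_max, y1_max,
#' feasible`) plus a JSON header (`<path>.json`) with the axes, window,
#' threshold and base parameters.
#'
#' @param grid A `sweep_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(grid, path) {
  df <- as.data.frame(grid)
  utils::write.csv(format(df, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  hdr <- list(package = "dormprey",
              version = as.character(utils::packageVersion("dormprey")),
              axis1 = list(parameter = grid$axis1$parameter,
                           values = grid$axis1$values),
              axis2 = list(parameter = grid$axis2$parameter,
                           values = grid$axis2$values),
              window = grid$window, threshold = grid$threshold,
              base_params = as.list(grid$base),
              base_params_hash = params_hash(grid$base))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 17, pretty = TRUE)
  invisible(path)
}

#' Export metric records
#'
#' Flat JSON records (metric, species where applicable, value, units,
#' parameter hash), the exchange format of the metrics CLI.
#'
#' @param records Named list of metric values (may contain `NA`).
#' @param params The `dormprey_params` the metrics were computed under.
#' @param path Output JSON path, or `NULL` to return the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_metrics <- function(records, params, path = NULL) {
  out <- list(package = "dormprey",
              version = as.character(utils::packageVersion("dormprey")),
              params_hash = params_hash(params),
              metrics = records)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = 17, pretty = TRUE,
                         null = "null", na = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
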