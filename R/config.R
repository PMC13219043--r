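#' Run configuration
#'
#' A validated bundle of algorithm parameters ([sparse_icp_params()] plus the
#' normal-estimation neighbourhood `k_neighbors`), phantom parameters
#' ([phantom_config()]), a seed, an output directory and a log level.
#' Defaults are the method's published operating point: `p = 0.5`,
#' `mu = 1.0`, `d_max = 5.0` mm, `k_max = 100`, `k_neighbors = 30`,
#' `n_probe = 30`.
#'
#' @param algorithm named list of [sparse_icp_params()] overrides, optionally
#'   with `k_neighbors`.
#' @param phantom named list of [phantom_config()] overrides.
#' @param seed integer seed.
#' @param output_dir output directory path.
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return A `run_config` list with fully-resolved `algorithm`, `k_neighbors`,
#'   `phantom`, `seed`, `output_dir`, `log_level`.
#' @export
run_config <- function(algorithm = list(), phantom = list(), seed = 1L,
                       output_dir = ".", log_level = "info") {
  if (!is.list(algorithm) || !is.list(phantom)) {
    stop("algorithm and phantom must be named lists", call. = FALSE)
  }
  kn <- algorithm$k_neighbors %||% 30L
  if (!is.numeric(kn) || kn < 3) {
    stop("invalid value for k_neighbors: must be >= 3", call. = FALSE)
  }
  algorithm$k_neighbors <- NULL
  unknown <- setdiff(names(algorithm), names(formals(sparse_icp_params)))
  if (length(unknown)) {
    stop(sprintf("unknown algorithm parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(phantom), names(formals(phantom_config)))
  if (length(unknown)) {
    stop(sprintf("unknown phantom parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  params <- tryCatch(do.call(sparse_icp_params, algorithm),
                     error = function(e) {
                       stop(sprintf("invalid algorithm configuration: %s",
                                    conditionMessage(e)), call. = FALSE)
                     })
  ph <- tryCatch(do.call(phantom_config, phantom),
                 error = function(e) {
                   stop(sprintf("invalid phantom configuration: %s",
                                conditionMessage(e)), call. = FALSE)
                 })
  if (!log_level %in% c("debug", "info", "warn", "error")) {
    stop(sprintf("invalid log_level '%s'", log_level), call. = FALSE)
  }
  structure(list(algorithm = params, k_neighbors = as.integer(kn), phantom = ph,
                 seed = as.integer(seed), output_dir = output_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Load a run configuration from JSON or YAML
#'
#' Missing fields fall back to the package defaults (`p = 0.5`, `mu = 1.0`,
#' `d_max = 5.0` mm, `k_max = 100`, `k_neighbors = 30`, `n_probe = 30`; an
#' empty document yields the all-defaults configuration). The document may
#' nest parameters under `algorithm:` / `phantom:` or give recognised keys at
#' the top level. Unknown keys and out-of-range values raise errors naming
#' the offending key. The fully resolved configuration is echoed to the log.
#'
#' @param path `.json`, `.yaml`/`.yml` file.
#' @param log_file optional JSON-lines log sink (see [nav_log()]).
#' @return A [run_config()].
#' @export
load_config <- function(path, log_file = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    if (file.size(path) == 0) list() else jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("config document must be a mapping", call. = FALSE)
  algo <- as.list(doc$algorithm %||% list())
  phan <- as.list(doc$phantom %||% list())
  rest <- doc[setdiff(names(doc), c("algorithm", "phantom", "seed",
                                    "output_dir", "log_level"))]
  algo_keys <- c(names(formals(sparse_icp_params)), "k_neighbors")
  phan_keys <- names(formals(phantom_config))
  for (k in names(rest)) {
    if (k %in% algo_keys) algo[[k]] <- rest[[k]]
    else if (k %in% phan_keys) phan[[k]] <- rest[[k]]
    else stop(sprintf("unknown configuration key: '%s'", k), call. = FALSE)
  }
  cfg <- run_config(algorithm = algo, phantom = phan,
                    seed = doc$seed %||% 1L,
                    output_dir = doc$output_dir %||% ".",
                    log_level = doc$log_level %||% "info")
  nav_log("info", "resolved configuration", unclass_config(cfg),
          log_file = log_file, log_level = cfg$log_level)
  cfg
}

unclass_config <- function(cfg) {
  list(algorithm = unclass(cfg$algorithm), k_neighbors = cfg$k_neighbors,
       phantom = unclass(cfg$phantom), seed = cfg$seed,
       output_dir = cfg$output_dir, log_level = cfg$log_level)
}

#' Structured logging
#'
#' Emits a human-readable message via [message()] (subject to `log_level`)
#' and, when `log_file` is given, appends one JSON object per event
#' (timestamp, level, message, data) — a machine-readable JSON-lines stream.
#'
#' @param level `"debug"`, `"info"`, `"warn"`, or `"error"`.
#' @param msg short message.
#' @param data optional named list serialized with the event.
#' @param log_file optional path to a JSON-lines file.
#' @param log_level minimum level to echo to the console.
#' @return Invisibly, `TRUE`.
#' @export
nav_log <- function(level = "info", msg = "", data = NULL, log_file = NULL,
                    log_level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[log_level]]) {
    message(sprintf("[%s] %s", level, msg))
  }
  if (!is.null(log_file)) {
    rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level = level,
                message = msg)
    if (!is.null(data)) rec$data <- data
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = log_file, append = TRUE, sep = "")
  }
  invisible(TRUE)
}
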