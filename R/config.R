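## Run configuration: the user's three inputs (data paths, data
## descriptions, final objective) plus run-level settings.

CONFIG_KEYS <- c("data", "goal", "blacklist", "backend", "output_dir", "limits")
LIMIT_KEYS <- c("max_repair_attempts", "temperature", "step_timeout")

#' Parse a run configuration document
#'
#' The agent takes three key inputs, supplied as YAML: an ordered list of
#' `path: description` data entries, a free-text final objective (`goal`),
#' and optionally a software blacklist, a backend profile and run limits.
#' Defaults are filled for everything optional; unknown keys are rejected
#' so typos never silently change a run.
#'
#' @param text A length-one character string holding the YAML document, or
#'   a character vector of lines.
#' @param base_dir Directory against which relative paths in the document
#'   are interpreted (recorded on the result; paths themselves are kept as
#'   given).
#' @return An object of class `analysis_config` with fields
#'   `data_entries` (data frame with columns `path`, `description`),
#'   `global_goal`, `blacklist`, `backend_profile`, `output_dir`,
#'   `max_repair_attempts`, `decoding_temperature` and `step_timeout`.
#' @examples
#' cfg <- parse_config("
#' data:
#'   - ./data/sample1.fastq.gz: single-end reads, condition A
#'   - ./data/genome.fa: reference genome
#' goal: identify differentially expressed genes
#' ")
#' cfg$global_goal
#' @export
parse_config <- function(text, base_dir = ".") {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  if (!is_nonempty_string(text)) {
    parse_error("configuration document is empty")
  }
  doc <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      parse_error(sprintf("malformed configuration document: %s",
                          conditionMessage(e)))
    }
  )
  if (!is.list(doc)) parse_error("configuration document is not a mapping")

  unknown <- setdiff(names(doc), CONFIG_KEYS)
  if (length(unknown)) {
    validation_error(sprintf("unknown configuration key(s): %s",
                             paste(unknown, collapse = ", ")))
  }

  missing <- setdiff(c("data", "goal"), names(doc))
  if (length(missing)) {
    validation_error(sprintf("missing required field(s): %s",
                             paste(missing, collapse = ", ")))
  }

  entries <- parse_data_entries(doc$data)
  if (anyDuplicated(entries$path)) {
    dup <- unique(entries$path[duplicated(entries$path)])
    validation_error(sprintf("duplicate data path(s): %s",
                             paste(dup, collapse = ", ")))
  }

  goal <- doc$goal
  if (!is_nonempty_string(goal)) {
    validation_error("field 'goal' must be a non-empty string")
  }

  blacklist <- dedup_blacklist(doc$blacklist)

  limits <- doc$limits %||% list()
  if (!is.list(limits)) validation_error("field 'limits' must be a mapping")
  unknown <- setdiff(names(limits), LIMIT_KEYS)
  if (length(unknown)) {
    validation_error(sprintf("unknown limits key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  max_repair <- limits$max_repair_attempts %||% 5L
  if (!is_count(max_repair)) {
    validation_error("limits.max_repair_attempts must be a non-negative integer")
  }
  temperature <- limits$temperature %||% 0
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature < 0) {
    validation_error("limits.temperature must be a real number >= 0")
  }
  step_timeout <- limits$step_timeout %||% 3600
  if (!is.numeric(step_timeout) || length(step_timeout) != 1L ||
      step_timeout <= 0) {
    validation_error("limits.step_timeout must be a positive number of seconds")
  }

  structure(
    list(
      data_entries = entries,
      global_goal = goal,
      blacklist = blacklist,
      backend_profile = doc$backend %||% "chat_api",
      output_dir = doc$output_dir %||% "./omicsagent_runs",
      max_repair_attempts = as.integer(max_repair),
      decoding_temperature = as.numeric(temperature),
      step_timeout = as.numeric(step_timeout),
      base_dir = base_dir
    ),
    class = "analysis_config"
  )
}

#' Read a run configuration file
#'
#' @param path Path to a YAML configuration file.
#' @return An `analysis_config`; relative paths are interpreted against the
#'   file's directory.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("configuration file not found: %s", path))
  parse_config(readLines(path, warn = FALSE), base_dir = dirname(path))
}

# `data` may be an ordered list of single-pair mappings (the documented
# form) or one mapping; both preserve order as YAML presents it.
parse_data_entries <- function(data) {
  if (is.null(data) || length(data) == 0L) {
    validation_error("field 'data' must contain at least one entry")
  }
  if (is.list(data) && is.null(names(data))) {
    paths <- character(0)
    descs <- character(0)
    for (item in data) {
      if (!is.list(item) || length(item) != 1L || is.null(names(item))) {
        validation_error(
          "each 'data' entry must be a single 'path: description' pair")
      }
      paths <- c(paths, names(item))
      descs <- c(descs, as.character(item[[1]]))
    }
  } else if (!is.null(names(data))) {
    paths <- names(data)
    descs <- vapply(data, as.character, "")
  } else {
    validation_error("field 'data' must be a list of 'path: description' pairs")
  }
  if (any(!nzchar(paths)) || any(is.na(descs)) || any(!nzchar(descs))) {
    validation_error("data paths and descriptions must be non-empty")
  }
  data.frame(path = paths, description = unname(descs),
             stringsAsFactors = FALSE)
}

# unique after case-folding, keeping first spelling seen
dedup_blacklist <- function(x) {
  if (is.null(x)) return(character(0))
  x <- as.character(unlist(x, use.names = FALSE))
  x[!duplicated(tolower(x))]
}

#' Serialize a run configuration back to YAML
#'
#' `parse_config(serialize_config(cfg))` reproduces `cfg` field for field,
#' which is how the resolved configuration written into a run's log
#' directory stays re-loadable.
#'
#' @param config An `analysis_config`.
#' @return A single YAML string.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  data <- lapply(seq_len(nrow(config$data_entries)), function(i) {
    stats::setNames(list(config$data_entries$description[i]),
                    config$data_entries$path[i])
  })
  doc <- list(
    data = data,
    goal = config$global_goal,
    blacklist = as.list(config$blacklist),
    backend = config$backend_profile,
    output_dir = config$output_dir,
    limits = list(
      max_repair_attempts = config$max_repair_attempts,
      temperature = config$decoding_temperature,
      step_timeout = config$step_timeout
    )
  )
  yaml::as.yaml(doc)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  goal:     ", x$global_goal, "\n", sep = "")
  cat("  data:     ", nrow(x$data_entries), " entr",
      if (nrow(x$data_entries) == 1L) "y" else "ies", "\n", sep = "")
  cat("  blacklist:", if (length(x$blacklist))
    paste(x$blacklist, collapse = ", ") else "(none)", "\n")
  cat("  backend:  ", x$backend_profile, "\n", sep = "")
  cat("  limits:    max_repair_attempts=", x$max_repair_attempts,
      ", temperature=", x$decoding_temperature,
      ", step_timeout=", x$step_timeout, "s\n", sep = "")
  invisible(x)
}

#' Materialize a run workspace
#'
#' Creates the directory tree for one run under the configured output
#' directory: `scripts/` (every generated script, one file per attempt),
#' `output/` (working directory for executed code), `logs/` (the
#' JSON-lines event stream and the resolved configuration copy).
#'
#' @param config An `analysis_config`.
#' @param run_id Identifier for this run; distinct run ids never share a
#'   root. Defaults to a timestamp-derived id.
#' @param overwrite Reuse an existing root for the same `run_id`?
#' @return An object of class `workspace` with fields `root`,
#'   `scripts_dir`, `output_dir`, `logs_dir`, `run_id`.
#' @export
init_workspace <- function(config, run_id = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(run_id)) {
    run_id <- paste0("run-", format(Sys.time(), "%Y%m%d-%H%M%S"), "-",
                     Sys.getpid())
  }
  if (!is_nonempty_string(run_id)) validation_error("run_id must be a non-empty string")
  out_root <- config$output_dir
  if (!is_abs_path(out_root)) out_root <- file.path(config$base_dir, out_root)
  root <- file.path(out_root, run_id)
  if (dir.exists(root)) {
    if (!overwrite) {
      validation_error(sprintf(
        "workspace for run_id '%s' already exists at %s (use overwrite)",
        run_id, root))
    }
    unlink(root, recursive = TRUE)  # overwrite means a clean workspace
  }
  ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) io_error(sprintf("cannot create workspace root: %s", root))
  ws <- structure(
    list(
      root = normalizePath(root),
      scripts_dir = file.path(normalizePath(root), "scripts"),
      output_dir = file.path(normalizePath(root), "output"),
      logs_dir = file.path(normalizePath(root), "logs"),
      run_id = run_id
    ),
    class = "workspace"
  )
  for (d in c(ws$scripts_dir, ws$output_dir, ws$logs_dir)) {
    dir.create(d, showWarnings = FALSE)
    if (!dir.exists(d)) io_error(sprintf("cannot create directory: %s", d))
  }
  writeLines(serialize_config(config), file.path(ws$logs_dir, "config.yaml"))
  ws
}

#' @export
print.workspace <- function(x, ...) {
  cat("<workspace> run_id=", x$run_id, "\n  root: ", x$root, "\n", sep = "")
  invisible(x)
}

is_abs_path <- function(p) {
  grepl("^(/|[A-Za-z]:[\\\\/]|\\\\\\\\)", p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
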