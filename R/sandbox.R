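## Confined execution of generated shell code: denylist screening,
## workspace-confined execution with timeouts, and outcome classification.

#' Default command denylist
#'
#' Perl-regex patterns applied to each effective script line by
#' [screen_commands()]: privilege escalation (`sudo`, `su`), machine
#' state (`shutdown`, `reboot`, `mkfs`, `dd` onto a block device),
#' destructive or permission-changing operations on absolute paths
#' outside the workspace (generated code addresses the workspace with
#' relative paths), and piping a download straight into a shell.
#'
#' @return Character vector of patterns.
#' @export
default_denylist <- function() {
  c(
    "(^|[;&|]\\s*)sudo(\\s|$)",
    "(^|[;&|]\\s*)su(\\s|$)",
    "\\bshutdown\\b",
    "\\breboot\\b",
    "\\bmkfs(\\.|\\b)",
    "\\bdd\\b[^;|&]*\\bof=/dev/",
    "\\brm\\b[^;|&]*\\s/[^\\s]+",
    "\\b(chmod|chown)\\b[^;|&]*\\s/[^\\s]+",
    "\\b(curl|wget)\\b[^;|&]*\\|\\s*(ba|z|da)?sh\\b"
  )
}

#' Default error patterns
#'
#' Fixed strings searched in captured stdout/stderr by [detect_error()].
#' Error detection is exit-code-primary; these patterns catch tools that
#' fail while still exiting 0. Plain non-empty stderr is deliberately NOT
#' an error: many bioinformatics tools log progress there.
#'
#' @return Character vector of fixed strings.
#' @export
default_error_patterns <- function() {
  c("command not found", "No such file or directory", "Traceback",
    "Error:", "error:", "Segmentation fault", "Killed")
}

#' Construct a sandbox policy
#'
#' @param denylist Command patterns, see [default_denylist()].
#' @param confine_to_workspace Run with the workspace root as working
#'   directory and a private, allow-listed environment?
#' @param container_mode Delegate execution to a container with only the
#'   workspace bind-mounted (requires `docker`)?
#' @param container_image Image used in container mode.
#' @param timeout Per-script wall-clock limit in seconds.
#' @param capture_limit Bytes kept per output stream (tail-preserving).
#' @return A `sandbox_policy`.
#' @export
sandbox_policy <- function(denylist = default_denylist(),
                           confine_to_workspace = TRUE,
                           container_mode = FALSE,
                           container_image = "ubuntu:22.04",
                           timeout = 3600,
                           capture_limit = 1048576) {
  if (!is.numeric(timeout) || timeout <= 0) validation_error("timeout must be > 0")
  if (!is.numeric(capture_limit) || capture_limit <= 0) {
    validation_error("capture_limit must be > 0")
  }
  structure(
    list(denylist = denylist, confine_to_workspace = confine_to_workspace,
         container_mode = container_mode, container_image = container_image,
         timeout = timeout, capture_limit = capture_limit),
    class = "sandbox_policy"
  )
}

error_finding <- function(is_error, excerpt = "",
                          reason = c("none", "nonzero_exit", "timeout",
                                     "denylisted_command", "error_pattern")) {
  reason <- match.arg(reason)
  if (!is_error) excerpt <- ""
  structure(list(is_error = is_error, excerpt = excerpt, reason = reason),
            class = "error_finding")
}

## Screening -------------------------------------------------------------

# effective lines: whole-line comments and here-doc bodies excluded
effective_lines <- function(shell_text) {
  lines <- strsplit(shell_text, "\n", fixed = TRUE)[[1]]
  keep <- logical(length(lines))
  terminator <- NULL
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!is.null(terminator)) {
      if (identical(trimws(line), terminator)) terminator <- NULL
      next
    }
    if (grepl("^\\s*#", line) || !nzchar(trimws(line))) next
    keep[i] <- TRUE
    m <- regmatches(line,
                    regexpr("<<-?\\s*['\"]?([A-Za-z_][A-Za-z0-9_]*)['\"]?",
                            line, perl = TRUE))
    if (length(m)) {
      terminator <- gsub("^<<-?\\s*['\"]?|['\"]?$", "", m)
    }
  }
  data.frame(line = which(keep), text = lines[keep], stringsAsFactors = FALSE)
}

#' Screen a script against the command denylist
#'
#' Tokenizes the script line-wise (whole-line comments and here-document
#' bodies excluded) and matches every effective line against the policy's
#' denylist patterns. Any match rejects the script, listing every
#' offending line; the orchestrator surfaces a rejection to the repair
#' loop as an `error_finding` with reason `denylisted_command`, so the
#' agent regenerates rather than aborts. Rejected scripts are never
#' executed.
#'
#' @param shell_text Script text.
#' @param policy A [sandbox_policy()].
#' @return A list with `accepted` (flag) and `offenses` (data frame with
#'   columns `line`, `text`, `pattern`; zero rows when accepted).
#' @export
screen_commands <- function(shell_text, policy = sandbox_policy()) {
  eff <- effective_lines(shell_text)
  offenses <- data.frame(line = integer(0), text = character(0),
                         pattern = character(0), stringsAsFactors = FALSE)
  for (pat in policy$denylist) {
    hit <- grepl(pat, eff$text, perl = TRUE)
    if (any(hit)) {
      offenses <- rbind(offenses, data.frame(
        line = eff$line[hit], text = eff$text[hit], pattern = pat,
        stringsAsFactors = FALSE))
    }
  }
  offenses <- offenses[order(offenses$line), , drop = FALSE]
  rownames(offenses) <- NULL
  list(accepted = nrow(offenses) == 0L, offenses = offenses)
}

## Execution -------------------------------------------------------------

execution_result <- function(exit_code, stdout_capture, stderr_capture,
                             duration, timed_out,
                             stdout_truncated = FALSE,
                             stderr_truncated = FALSE) {
  structure(
    list(exit_code = as.integer(exit_code), stdout_capture = stdout_capture,
         stderr_capture = stderr_capture, duration = duration,
         timed_out = timed_out, stdout_truncated = stdout_truncated,
         stderr_truncated = stderr_truncated),
    class = "execution_result"
  )
}

TIMEOUT_EXIT <- 124L  # conventional kill sentinel

read_capture <- function(path, limit) {
  if (!file.exists(path)) return(list(text = "", truncated = FALSE))
  size <- file.info(path)$size
  txt <- tryCatch(
    readChar(path, nchars = size, useBytes = TRUE),
    error = function(e) ""
  )
  truncated <- FALSE
  if (nchar(txt, type = "bytes") > limit) {
    # tail-preserving: errors trail
    txt <- substr(txt, nchar(txt) - limit + 1L, nchar(txt))
    truncated <- TRUE
  }
  list(text = txt, truncated = truncated)
}

#' Execute a screened code block in the workspace
#'
#' Writes the script to `scripts_dir/step<N>_attempt<K>.sh` with
#' `set -e` prepended (fail-fast: multi-command steps report the first
#' failing command), then runs it through a POSIX shell with the
#' workspace root as working directory and a private environment holding
#' only allow-listed variables (`PATH`, `HOME`, `LANG`, `LC_ALL`, and a
#' `TMPDIR` inside the workspace). Both streams are captured to files
#' beside the script (tail-truncated at the capture limit) and the
#' process is killed at the policy timeout. In container mode the script
#' runs inside a container with the workspace bind-mounted and no other
#' mounts. The result is persisted as JSON beside the script before
#' return.
#'
#' @param code A `code_block` accepted by [screen_commands()].
#' @param workspace A `workspace` from [init_workspace()].
#' @param policy A [sandbox_policy()].
#' @return An `execution_result` with fields `exit_code`,
#'   `stdout_capture`, `stderr_capture`, `duration`, `timed_out`.
#' @export
execute_code <- function(code, workspace, policy = sandbox_policy()) {
  stopifnot(inherits(code, "code_block"), inherits(workspace, "workspace"))
  stem <- sprintf("step%d_attempt%d", code$step_index, code$attempt)
  script <- file.path(workspace$scripts_dir, paste0(stem, ".sh"))
  writeLines(c("set -e", code$shell_text), script)
  out_file <- file.path(workspace$scripts_dir, paste0(stem, "_stdout.txt"))
  err_file <- file.path(workspace$scripts_dir, paste0(stem, "_stderr.txt"))

  tmpdir <- file.path(workspace$root, "tmp")
  dir.create(tmpdir, showWarnings = FALSE)

  if (policy$container_mode) {
    if (!nzchar(Sys.which("docker"))) {
      infra_error("container mode requested but docker is not available")
    }
    cmd <- "docker"
    args <- c("run", "--rm",
              "-v", paste0(workspace$root, ":/ws"), "-w", "/ws",
              policy$container_image, "sh",
              paste0("/ws/scripts/", basename(script)))
  } else {
    cmd <- "env"
    args <- c("-i",
              paste0("PATH=", Sys.getenv("PATH")),
              paste0("HOME=", workspace$root),
              paste0("LANG=", Sys.getenv("LANG", "C")),
              paste0("LC_ALL=", Sys.getenv("LC_ALL", "C")),
              paste0("TMPDIR=", tmpdir),
              "sh", script)
  }

  old_wd <- getwd()
  on.exit(setwd(old_wd), add = TRUE)
  if (policy$confine_to_workspace) setwd(workspace$root)

  t0 <- Sys.time()
  status <- suppressWarnings(
    system2(cmd, args, stdout = out_file, stderr = err_file,
            timeout = policy$timeout)
  )
  duration <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  timed_out <- identical(as.integer(status), TIMEOUT_EXIT) &&
    duration >= policy$timeout
  if (timed_out) status <- TIMEOUT_EXIT

  so <- read_capture(out_file, policy$capture_limit)
  se <- read_capture(err_file, policy$capture_limit)
  result <- execution_result(status, so$text, se$text, duration, timed_out,
                             so$truncated, se$truncated)
  result_json <- file.path(workspace$scripts_dir, paste0(stem, "_result.json"))
  jsonlite::write_json(unclass(result), result_json, auto_unbox = TRUE,
                       digits = NA)
  result
}

## Classification --------------------------------------------------------

#' Classify an execution result
#'
#' A pure function of the result and the pattern list:
#' `is_error = (exit_code != 0) | timed_out | any pattern matches either
#' capture`. Exit code 0 with no pattern match is a success even when
#' stderr is non-empty (aligners and other tools log progress there).
#' The excerpt is the matched region with surrounding context when a
#' pattern fired, otherwise the tail of stderr (falling back to the tail
#' of stdout).
#'
#' @param result An `execution_result`.
#' @param patterns Fixed strings, see [default_error_patterns()].
#' @param context Characters of context kept around a pattern match.
#' @return An `error_finding` with fields `is_error`, `excerpt`,
#'   `reason` (`nonzero_exit`, `timeout`, `error_pattern`, or `none`).
#' @export
detect_error <- function(result, patterns = default_error_patterns(),
                         context = 200L) {
  stopifnot(inherits(result, "execution_result"))
  match_excerpt <- function() {
    for (stream in list(result$stderr_capture, result$stdout_capture)) {
      for (pat in patterns) {
        i <- regexpr(pat, stream, fixed = TRUE)
        if (i > 0) {
          from <- max(1L, i - context)
          to <- min(nchar(stream), i + attr(i, "match.length") + context)
          return(substr(stream, from, to))
        }
      }
    }
    NULL
  }
  fallback_excerpt <- function() {
    if (nzchar(result$stderr_capture)) return(tail_chars(result$stderr_capture, 4000L))
    tail_chars(result$stdout_capture, 4000L)
  }
  matched <- match_excerpt()
  if (result$timed_out) {
    return(error_finding(TRUE,
                         excerpt = paste0("execution timed out; ",
                                          fallback_excerpt()),
                         reason = "timeout"))
  }
  if (result$exit_code != 0L) {
    return(error_finding(TRUE,
                         excerpt = if (!is.null(matched)) matched else fallback_excerpt(),
                         reason = "nonzero_exit"))
  }
  if (!is.null(matched)) {
    return(error_finding(TRUE, excerpt = matched, reason = "error_pattern"))
  }
  error_finding(FALSE, reason = "none")
}
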