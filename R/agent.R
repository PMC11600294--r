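## Orchestration of a full run:
## plan -> per-step codegen -> screen -> execute -> repair -> memory -> report.

HISTORY_TOKEN_BUDGET <- 3000L  # ~12000 characters of memory per prompt

#' Run the agent end to end
#'
#' Executes the three phases on one configuration: proposes a plan (with
#' a blacklist re-proposal loop), then for each step in order generates
#' code, screens it against the denylist, executes it in the workspace
#' and runs the automatic repair cycle on failure. A successfully
#' executed step is appended to the agent's memory; the first step that
#' exhausts its repair bound stops the run and the remaining steps are
#' marked skipped (downstream steps consume upstream outputs, so
#' continuing would be meaningless). A `run_report` is always returned
#' and written to the workspace log directory.
#'
#' @param config An [parse_config()] result.
#' @param backend A backend object; defaults to resolving
#'   `config$backend_profile` with workspace placeholders declared for
#'   transcript normalization.
#' @param run_id,overwrite Passed to [init_workspace()].
#' @param policy A [sandbox_policy()]; defaults to one with the
#'   configured step timeout.
#' @param workspace_setup Optional function called with the freshly
#'   initialized `workspace` before the run starts; fixture harnesses use
#'   it to stage input data and stub tools inside the workspace root.
#' @return A `run_report` with the plan, per-step outcomes (status,
#'   attempt count, final script reference) and the three stage flags
#'   `plan_ok`, `all_codegen_ok`, `end_to_end_ok`.
#' @export
run_agent <- function(config, backend = NULL, run_id = NULL,
                      overwrite = FALSE, policy = NULL,
                      workspace_setup = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  ws <- init_workspace(config, run_id = run_id, overwrite = overwrite)
  if (!is.null(workspace_setup)) workspace_setup(ws)
  if (is.null(policy)) policy <- sandbox_policy(timeout = config$step_timeout)
  log <- log_open(file.path(ws$logs_dir, "run.jsonl"))
  started <- Sys.time()
  log_event(log, "run_start",
            list(run_id = ws$run_id, goal = config$global_goal,
                 backend = config$backend_profile))

  if (is.null(backend)) {
    backend <- resolve_backend(
      config$backend_profile,
      placeholders = c(WORKSPACE = ws$root, RUN_ID = ws$run_id))
  }

  history <- list()
  mk_ctx <- function(goal) {
    prompt_context(config$blacklist, config$data_entries, goal,
                   summarize_history(history, HISTORY_TOKEN_BUDGET))
  }

  finish <- function(plan, outcomes, plan_ok) {
    statuses <- outcomes$status
    all_codegen_ok <- plan_ok && length(statuses) > 0 &&
      all(outcomes$codegen_ok)
    end_to_end_ok <- plan_ok && length(statuses) > 0 &&
      all(statuses == "success")
    report <- structure(
      list(run_id = ws$run_id, plan = plan, step_outcomes = outcomes,
           stage_flags = list(plan_ok = plan_ok,
                              all_codegen_ok = all_codegen_ok,
                              end_to_end_ok = end_to_end_ok),
           started = format(started, "%Y-%m-%dT%H:%M:%OS3%z"),
           ended = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")),
      class = "run_report"
    )
    payload <- report_to_list(report)
    jsonlite::write_json(payload, file.path(ws$logs_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    log_event(log, "run_report", payload)
    report
  }

  empty_outcomes <- function(n = 0L) {
    data.frame(step = integer(n), status = character(n),
               attempts = integer(n), codegen_ok = logical(n),
               final_script = character(n), stringsAsFactors = FALSE)
  }

  ## Planning phase (with blacklist re-proposal loop)
  plan <- NULL
  extra <- NULL
  for (round in seq_len(config$max_repair_attempts + 1L)) {
    plan_try <- tryCatch(
      propose_plan(backend, mk_ctx(config$global_goal),
                   max_attempts = config$max_repair_attempts,
                   temperature = config$decoding_temperature,
                   profile = config$backend_profile, extra = extra, log = log),
      agent_planning_error = function(e) e
    )
    if (inherits(plan_try, "agent_planning_error")) {
      log_event(log, "planning_failed", list(message = conditionMessage(plan_try)))
      return(finish(NULL, empty_outcomes(), plan_ok = FALSE))
    }
    violations <- check_blacklist(plan_try, config$blacklist)
    if (nrow(violations) == 0L) {
      plan <- plan_try
      break
    }
    log_event(log, "blacklist_violation",
              list(violations = violations, round = round))
    extra <- paste0(
      "Your previous plan used blacklisted software (",
      paste(unique(violations$software), collapse = ", "),
      "). Propose a new plan that avoids every blacklisted tool.")
  }
  if (is.null(plan)) {
    log_event(log, "planning_failed",
              list(message = "blacklist violations persisted across re-proposals"))
    return(finish(NULL, empty_outcomes(), plan_ok = FALSE))
  }
  log_event(log, "plan_accepted",
            list(n_steps = length(plan$steps),
                 steps = vapply(plan$steps, function(s) s$description, "")))

  history[[1]] <- history_record(
    "input_and_plan", data_entries = config$data_entries,
    global_goal = config$global_goal,
    plan_tasks = vapply(plan$steps, function(s) s$description, ""))

  ## Per-step codegen / screen / execute / repair
  n <- length(plan$steps)
  outcomes <- empty_outcomes(n)
  outcomes$step <- seq_len(n)
  outcomes$status <- "skipped"
  outcomes$final_script <- ""
  failed <- FALSE

  for (s in plan$steps) {
    i <- s$index
    if (failed) {
      log_event(log, "step_skipped", list(step = i))
      next
    }
    ctx <- mk_ctx(s$description)
    code <- tryCatch(
      generate_code(backend, ctx, s,
                    max_attempts = config$max_repair_attempts,
                    temperature = config$decoding_temperature,
                    profile = config$backend_profile, log = log),
      agent_codegen_error = function(e) e
    )
    if (inherits(code, "agent_codegen_error")) {
      log_event(log, "step_failed",
                list(step = i, stage = "codegen",
                     message = conditionMessage(code)))
      outcomes$status[i] <- "failed"
      outcomes$codegen_ok[i] <- FALSE
      failed <- TRUE
      next
    }
    outcomes$codegen_ok[i] <- TRUE

    executor <- function(cb) {
      scr <- screen_commands(cb$shell_text, policy)
      if (!scr$accepted) {
        rejected <- file.path(ws$scripts_dir,
                              sprintf("step%d_attempt%d_rejected.sh",
                                      cb$step_index, cb$attempt))
        writeLines(cb$shell_text, rejected)
        log_event(log, "screen_rejected",
                  list(step = cb$step_index, attempt = cb$attempt,
                       offenses = scr$offenses))
        return(list(result = NULL, finding = error_finding(
          TRUE,
          excerpt = paste0("script rejected by command screening:\n",
                           paste(scr$offenses$text, collapse = "\n")),
          reason = "denylisted_command")))
      }
      res <- execute_code(cb, ws, policy)
      log_event(log, "execution",
                list(step = cb$step_index, attempt = cb$attempt,
                     exit_code = res$exit_code, timed_out = res$timed_out,
                     duration = res$duration))
      res
    }

    rl <- repair_loop(backend, ctx, s, code, executor,
                      max_repair_attempts = config$max_repair_attempts,
                      temperature = config$decoding_temperature,
                      profile = config$backend_profile, log = log)
    outcomes$attempts[i] <- length(rl$attempts)
    last <- rl$attempts[[length(rl$attempts)]]
    outcomes$final_script[i] <- sprintf("step%d_attempt%d.sh",
                                        i, last$code$attempt)
    if (rl$success) {
      outcomes$status[i] <- "success"
      history[[length(history) + 1L]] <- history_record(
        "task_completed", task = s$description,
        code = last$code$shell_text)
      log_event(log, "step_success", list(step = i,
                                          attempts = length(rl$attempts)))
    } else {
      outcomes$status[i] <- "failed"
      log_event(log, "step_failed",
                list(step = i, stage = "execute",
                     attempts = length(rl$attempts)))
      failed <- TRUE
    }
  }

  finish(plan, outcomes, plan_ok = TRUE)
}

## Report serialization --------------------------------------------------

report_to_list <- function(report) {
  plan <- report$plan
  plan_list <- if (is.null(plan)) NULL else list(
    raw_text = plan$raw_text,
    steps = lapply(plan$steps, function(s) list(
      index = s$index, description = s$description,
      software = as.list(s$software),
      inputs_mentioned = as.list(s$inputs_mentioned)))
  )
  oc <- report$step_outcomes
  list(
    run_id = report$run_id,
    plan = plan_list,
    step_outcomes = lapply(seq_len(nrow(oc)), function(i) list(
      step = oc$step[i], status = oc$status[i], attempts = oc$attempts[i],
      codegen_ok = oc$codegen_ok[i], final_script = oc$final_script[i])),
    stage_flags = report$stage_flags,
    started = report$started,
    ended = report$ended
  )
}

report_from_list <- function(x) {
  plan <- NULL
  if (!is.null(x$plan)) {
    steps <- lapply(x$plan$steps, function(s) plan_step(
      as.integer(s$index), s$description,
      software = as.character(unlist(s$software)),
      inputs_mentioned = as.character(unlist(s$inputs_mentioned))))
    plan <- new_plan(steps, x$plan$raw_text)
  }
  oc <- x$step_outcomes
  outcomes <- data.frame(
    step = vapply(oc, function(o) as.integer(o$step), 1L),
    status = vapply(oc, function(o) o$status, ""),
    attempts = vapply(oc, function(o) as.integer(o$attempts), 1L),
    codegen_ok = vapply(oc, function(o) isTRUE(o$codegen_ok), TRUE),
    final_script = vapply(oc, function(o) o$final_script %||% "", ""),
    stringsAsFactors = FALSE
  )
  structure(
    list(run_id = x$run_id, plan = plan, step_outcomes = outcomes,
         stage_flags = list(plan_ok = isTRUE(x$stage_flags$plan_ok),
                            all_codegen_ok = isTRUE(x$stage_flags$all_codegen_ok),
                            end_to_end_ok = isTRUE(x$stage_flags$end_to_end_ok)),
         started = x$started, ended = x$ended),
    class = "run_report"
  )
}

#' Reconstruct a run report from a recorded run log
#'
#' Re-executes nothing: reads the JSON-lines event stream (or the
#' `report.json` written beside it) and rebuilds the `run_report` the run
#' produced.
#'
#' @param path Path to a run's `run.jsonl`, its `report.json`, its log
#'   directory, or the workspace root.
#' @return A `run_report`.
#' @export
replay_run <- function(path) {
  if (dir.exists(path)) {
    cand <- c(file.path(path, "run.jsonl"), file.path(path, "logs", "run.jsonl"))
    hit <- cand[file.exists(cand)]
    if (!length(hit)) io_error(sprintf("no run log found under %s", path))
    path <- hit[1]
  }
  if (grepl("\\.json$", path)) {
    return(report_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE)))
  }
  events <- read_log_events(path)
  reports <- Filter(function(e) identical(e$event, "run_report"), events)
  if (!length(reports)) io_error("run log contains no run_report event")
  report_from_list(reports[[length(reports)]]$payload)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> run_id=", x$run_id, "\n", sep = "")
  f <- x$stage_flags
  cat(sprintf("  stages: plan_ok=%s all_codegen_ok=%s end_to_end_ok=%s\n",
              f$plan_ok, f$all_codegen_ok, f$end_to_end_ok))
  oc <- x$step_outcomes
  if (nrow(oc)) {
    for (i in seq_len(nrow(oc))) {
      cat(sprintf("  step %d: %s (attempts=%d)\n",
                  oc$step[i], oc$status[i], oc$attempts[i]))
    }
  } else {
    cat("  (no step outcomes)\n")
  }
  invisible(x)
}
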