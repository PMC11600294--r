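## Prompt construction and agent memory.
##
## Every prompt is assembled from four named slots -- blacklist, data list,
## current goal, history summary -- rendered into versioned template files
## under inst/templates/.  Slot values are delimiter-escaped so that a
## rendered prompt can always be parsed back into its slots, which is what
## the transcript backend and the slot round-trip tests rely on.

## Slot escaping --------------------------------------------------------
## Percent-encodes only the section markers (and % itself), so decoding is
## order-independent apart from %25 being decoded last.

escape_slot <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("<<", "%3C", x, fixed = TRUE)
  x <- gsub(">>", "%3E", x, fixed = TRUE)
  x
}

unescape_slot <- function(x) {
  x <- gsub("%3C", "<<", x, fixed = TRUE)
  x <- gsub("%3E", ">>", x, fixed = TRUE)
  x <- gsub("%25", "%", x, fixed = TRUE)
  x
}

BLACKLIST_NONE <- "none"
HISTORY_NONE <- "No prior actions."

read_template <- function(name) {
  path <- system.file("templates", name, package = "omicsagent")
  if (!nzchar(path)) io_error(sprintf("missing template: %s", name))
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

fill_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{{", key, "}}"), values[[key]],
                     template, fixed = TRUE)
  }
  template
}

## History records ------------------------------------------------------

#' Create a history record
#'
#' The agent's memory is an ordered list of records: exactly one
#' `input_and_plan` record (always first), then one `task_completed`
#' record per successfully executed step, in execution order.
#'
#' @param kind `"input_and_plan"` or `"task_completed"`.
#' @param data_entries For `input_and_plan`: the data frame of
#'   `path`/`description` pairs the user supplied.
#' @param global_goal For `input_and_plan`: the final objective.
#' @param plan_tasks For `input_and_plan`: character vector of planned
#'   sub-task descriptions, in order.
#' @param task For `task_completed`: the completed sub-goal text.
#' @param code For `task_completed`: the shell code that completed it.
#' @return A `history_record`.
#' @export
history_record <- function(kind = c("input_and_plan", "task_completed"),
                           data_entries = NULL, global_goal = NULL,
                           plan_tasks = NULL, task = NULL, code = NULL) {
  kind <- match.arg(kind)
  if (kind == "input_and_plan") {
    if (is.null(data_entries) || !is_nonempty_string(global_goal) ||
        is.null(plan_tasks) || !length(plan_tasks)) {
      contract_error("input_and_plan record needs data_entries, global_goal and plan_tasks")
    }
  } else {
    if (!is_nonempty_string(task) || !is_nonempty_string(code)) {
      contract_error("task_completed record needs non-empty task and code")
    }
  }
  structure(
    list(kind = kind, data_entries = data_entries, global_goal = global_goal,
         plan_tasks = plan_tasks, task = task, code = code,
         timestamp = Sys.time()),
    class = "history_record"
  )
}

validate_history <- function(records) {
  if (!length(records)) return(invisible(TRUE))
  kinds <- vapply(records, function(r) r$kind, "")
  if (kinds[1] != "input_and_plan") {
    contract_error("the first history record must be input_and_plan")
  }
  if (sum(kinds == "input_and_plan") != 1L) {
    contract_error("exactly one input_and_plan record is allowed per run")
  }
  invisible(TRUE)
}

format_data_list <- function(data_entries) {
  paste(data_entries$path, data_entries$description, sep = ": ")
}

#' Summarize the agent's memory into prompt text
#'
#' Renders history records into the two fixed memory sentence templates:
#' a planning-phase sentence ("First, you provided input in the format
#' 'file path: file description' in a list: ... Your plan involves ...")
#' followed by one "Then, you successfully completed the task: ... with
#' the corresponding code: ..." sentence per completed task.  When the
#' text would exceed the token budget, the oldest completed-task
#' sentences are elided and replaced by a count marker; the plan sentence
#' and the most recent task sentence are always retained.
#'
#' @param records List of [history_record()] objects, ordering-valid.
#' @param token_budget Approximate token budget (a character-count proxy
#'   of 4 characters per token is used); `Inf` disables elision.
#' @return A single string; empty records give `""`.
#' @export
summarize_history <- function(records, token_budget = Inf) {
  if (!length(records)) return("")
  validate_history(records)

  first <- records[[1]]
  plan_sentence <- paste0(
    "First, you provided input in the format 'file path: file description' ",
    "in a list: ", paste(format_data_list(first$data_entries), collapse = "; "),
    ". You devised a detailed plan to accomplish your overarching objective. ",
    "Your overarching goal is ", first$global_goal,
    ". Your plan involves ", paste(first$plan_tasks, collapse = "; "), "."
  )

  task_sentences <- vapply(records[-1], function(r) {
    paste0("Then, you successfully completed the task: ", r$task,
           " with the corresponding code: ", r$code, ".")
  }, "")

  char_budget <- 4 * token_budget
  assemble <- function(sentences, elided) {
    parts <- plan_sentence
    if (elided > 0L) {
      parts <- c(parts, sprintf("[%d earlier completed task%s elided.]",
                                elided, if (elided == 1L) "" else "s"))
    }
    paste(c(parts, sentences), collapse = " ")
  }

  elided <- 0L
  out <- assemble(task_sentences, elided)
  while (nchar(out) > char_budget && length(task_sentences) > 1L) {
    task_sentences <- task_sentences[-1]
    elided <- elided + 1L
    out <- assemble(task_sentences, elided)
  }
  out
}

## Prompt context -------------------------------------------------------

#' Create a prompt context
#'
#' The four slots every prompt is built from. `current_goal` holds the
#' global objective during planning and the step's sub-goal during code
#' generation.
#'
#' @param blacklist Character vector of prohibited software names (may be
#'   empty; rendered as an explicit "none" marker).
#' @param data_entries Data frame with columns `path` and `description`.
#' @param current_goal Non-empty goal text.
#' @param history_summary History text from [summarize_history()] (may be
#'   empty; rendered as an explicit "no prior actions" marker).
#' @return A `prompt_context`.
#' @export
prompt_context <- function(blacklist, data_entries, current_goal,
                           history_summary = "") {
  if (!is_nonempty_string(current_goal)) {
    contract_error("current_goal must be a non-empty string")
  }
  if (!is.data.frame(data_entries) ||
      !all(c("path", "description") %in% names(data_entries))) {
    contract_error("data_entries must have columns 'path' and 'description'")
  }
  if (!is.character(blacklist)) contract_error("blacklist must be character")
  if (!is_string(history_summary)) {
    contract_error("history_summary must be a single string")
  }
  structure(
    list(blacklist = blacklist, data_entries = data_entries,
         current_goal = current_goal, history_summary = history_summary),
    class = "prompt_context"
  )
}

slot_values <- function(ctx) {
  bl <- if (length(ctx$blacklist)) {
    paste(escape_slot(ctx$blacklist), collapse = "\n")
  } else {
    BLACKLIST_NONE
  }
  hist <- if (nzchar(ctx$history_summary)) {
    escape_slot(ctx$history_summary)
  } else {
    HISTORY_NONE
  }
  list(
    blacklist = bl,
    data_list = paste(escape_slot(format_data_list(ctx$data_entries)),
                      collapse = "\n"),
    current_goal = escape_slot(ctx$current_goal),
    history_summary = hist
  )
}

#' Render the planning-phase prompt
#'
#' @param ctx A [prompt_context()] whose `current_goal` is the global
#'   objective.
#' @return Prompt text containing all four slots; deterministic in `ctx`.
#' @export
render_planning_prompt <- function(ctx) {
  stopifnot(inherits(ctx, "prompt_context"))
  fill_template(read_template("planning_prompt.txt"), slot_values(ctx))
}

#' Render the code-generation prompt for one plan step
#'
#' @param ctx A [prompt_context()] whose `current_goal` equals the step's
#'   description (the sub-goal).
#' @param step A `plan_step` (see [parse_plan()]).
#' @return Prompt text instructing the backend to answer with exactly one
#'   fenced shell code block.
#' @export
render_codegen_prompt <- function(ctx, step) {
  stopifnot(inherits(ctx, "prompt_context"))
  if (!is_nonempty_string(step$description)) {
    contract_error("plan step has an empty description")
  }
  if (!identical(ctx$current_goal, step$description)) {
    contract_error("ctx$current_goal must equal the step description")
  }
  values <- slot_values(ctx)
  values$step_software <- if (length(step$software)) {
    paste(escape_slot(step$software), collapse = ", ")
  } else {
    "(planner named no specific tool)"
  }
  fill_template(read_template("codegen_prompt.txt"), values)
}

# Codegen prompt plus a previous-attempt section carrying the failed code
# and the captured error excerpt; used by the automatic code repair loop.
render_repair_prompt <- function(ctx, step, previous_code, error_excerpt) {
  base <- render_codegen_prompt(ctx, step)
  suffix <- fill_template(read_template("repair_suffix.txt"), list(
    previous_code = escape_slot(previous_code),
    error_excerpt = escape_slot(error_excerpt)
  ))
  paste0(base, suffix)
}

#' Recover the four slots from a rendered prompt
#'
#' Inverse of the renderers: extracts blacklist, data list, current goal
#' and history summary from a prompt, undoing slot escaping. Used to
#' verify slot completeness.
#'
#' @param text A rendered prompt.
#' @return A list with elements `blacklist` (character vector),
#'   `data_entries` (data frame), `current_goal`, `history_summary`
#'   (empty string when the prompt carries the "no prior actions" marker).
#' @export
extract_prompt_slots <- function(text) {
  grab <- function(name) {
    open <- paste0("<<", name, ">>\n")
    close <- paste0("\n<</", name, ">>")
    i <- regexpr(open, text, fixed = TRUE)
    if (i < 0) parse_error(sprintf("prompt lacks slot section %s", name))
    rest <- substr(text, i + attr(i, "match.length"), nchar(text))
    j <- regexpr(close, rest, fixed = TRUE)
    if (j < 0) parse_error(sprintf("prompt slot %s is unterminated", name))
    substr(rest, 1L, j - 1L)
  }
  bl_raw <- grab("BLACKLIST")
  blacklist <- if (identical(bl_raw, BLACKLIST_NONE)) {
    character(0)
  } else {
    unescape_slot(strsplit(bl_raw, "\n", fixed = TRUE)[[1]])
  }
  dl_lines <- unescape_slot(strsplit(grab("DATA_LIST"), "\n", fixed = TRUE)[[1]])
  sep <- regexpr(": ", dl_lines, fixed = TRUE)
  if (any(sep < 0)) parse_error("malformed 'path: description' line in data list")
  data_entries <- data.frame(
    path = substr(dl_lines, 1L, sep - 1L),
    description = substr(dl_lines, sep + 2L, nchar(dl_lines)),
    stringsAsFactors = FALSE
  )
  hist_raw <- grab("HISTORY_SUMMARY")
  history <- if (identical(hist_raw, HISTORY_NONE)) "" else unescape_slot(hist_raw)
  list(
    blacklist = blacklist,
    data_entries = data_entries,
    current_goal = unescape_slot(grab("CURRENT_GOAL")),
    history_summary = history
  )
}
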