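## Code-generation phase and the automatic code repair (ACR) cycle.

code_block <- function(step_index, shell_text, attempt = 1L,
                       source_response = "") {
  if (!is_nonempty_string(shell_text)) {
    contract_error("a code block must carry non-empty shell text")
  }
  structure(list(step_index = as.integer(step_index), shell_text = shell_text,
                 attempt = as.integer(attempt),
                 source_response = source_response),
            class = "code_block")
}

# command words that make an unfenced line look like shell; used only by
# the no-fence fallback heuristic
SHELLISH_WORDS <- c(
  "source", "conda", "pip", "export", "cd", "mkdir", "echo", "set", "env",
  "bash", "sh", "Rscript", "python", "python3", "wget", "curl", "gunzip",
  "gzip", "tar", "cat", "mv", "cp", "rm", "for", "do", "done", "if", "then",
  "fi", "samtools", "bcftools", "bedtools", "bwa", "bowtie", "bowtie2",
  "hisat2", "hisat2-build", "minimap2", "trimmomatic", "fastqc", "cutadapt",
  "macs2", "htseq-count", "featureCounts", "stringtie", "salmon"
)

#' Extract shell code from a backend response
#'
#' Returns the concatenation, in order, of all fenced code blocks tagged
#' as shell (` ```bash `, ` ```sh `, ` ```shell `, ` ```zsh `) or
#' untagged. When no fences are present, the whole text is accepted iff
#' at least 80 percent of its non-empty lines look like commands (start
#' with a known command word, a path, or a variable assignment).
#'
#' @param response_text Raw backend response.
#' @return The shell script text.
#' @export
extract_code <- function(response_text) {
  if (!is_string(response_text) || !nzchar(trimws(response_text))) {
    agent_abort("no extractable code: response is empty",
                "agent_extraction_error")
  }
  lines <- strsplit(response_text, "\n", fixed = TRUE)[[1]]
  fence <- grepl("^\\s*```", lines)
  if (any(fence)) {
    idx <- which(fence)
    if (length(idx) %% 2L == 1L) idx <- c(idx, length(lines) + 1L)
    blocks <- character(0)
    for (k in seq(1L, length(idx), by = 2L)) {
      open <- lines[idx[k]]
      tag <- tolower(trimws(sub("^\\s*```", "", open)))
      if (!tag %in% c("", "bash", "sh", "shell", "zsh")) next
      body <- lines[seq(idx[k] + 1L, idx[k + 1L] - 1L)]
      body <- paste(body, collapse = "\n")
      if (nzchar(trimws(body))) blocks <- c(blocks, body)
    }
    if (length(blocks)) return(paste(blocks, collapse = "\n"))
    agent_abort("no extractable code: fenced blocks are empty or not shell",
                "agent_extraction_error")
  }
  nonempty <- trimws(lines[nzchar(trimws(lines))])
  looks <- grepl(paste0("^(#|\\.?/|[A-Za-z_][A-Za-z0-9_]*=|",
                        paste(SHELLISH_WORDS, collapse = "|"), ")\\b"),
                 nonempty) |
    grepl("^(#|\\.?/|[A-Za-z_][A-Za-z0-9_]*=)", nonempty)
  if (length(nonempty) && mean(looks) >= 0.8) {
    return(paste(lines, collapse = "\n"))
  }
  agent_abort("no extractable code: response contains no fenced shell block",
              "agent_extraction_error")
}

#' Generate shell code for one plan step
#'
#' Renders the code-generation prompt for the step, asks the backend and
#' extracts the fenced shell code. On extraction failure (or a
#' non-`complete` response) the backend is re-asked with the diagnostic
#' appended, bounded by `max_attempts`.
#'
#' @param backend A backend object.
#' @param ctx A [prompt_context()] whose `current_goal` equals
#'   `step$description`.
#' @param step A `plan_step`.
#' @param max_attempts Bound on re-asks after the first failure.
#' @param temperature,profile Decoding settings.
#' @param log Optional run log (internal).
#' @return A `code_block`.
#' @export
generate_code <- function(backend, ctx, step, max_attempts = 5L,
                          temperature = 0, profile = "transcript",
                          log = NULL) {
  base_prompt <- render_codegen_prompt(ctx, step)
  responses <- list()
  diagnostic <- NULL
  for (attempt in seq_len(max_attempts + 1L)) {
    prompt <- base_prompt
    if (!is.null(diagnostic)) {
      prompt <- paste0(base_prompt,
                       "\n\nYour previous response was unusable: ", diagnostic,
                       "\nRespond again with exactly one fenced shell code block.")
    }
    log_event(log, "prompt", list(phase = "codegen", step = step$index,
                                  attempt = attempt, text = prompt))
    resp <- complete(backend, backend_request(prompt, temperature = temperature,
                                              profile = profile))
    log_event(log, "backend_response",
              list(phase = "codegen", step = step$index, attempt = attempt,
                   finish_state = resp$finish_state, text = resp$text))
    responses[[attempt]] <- resp
    if (resp$finish_state != "complete") {
      diagnostic <- paste0("backend returned state '", resp$finish_state, "'")
      next
    }
    code <- tryCatch(extract_code(resp$text),
                     agent_extraction_error = function(e) e)
    if (!inherits(code, "condition")) {
      return(code_block(step$index, code, attempt = 1L,
                        source_response = resp$text))
    }
    diagnostic <- conditionMessage(code)
  }
  agent_abort(
    sprintf("code generation for step %d failed after %d attempt(s): %s",
            step$index, max_attempts + 1L, diagnostic),
    "agent_codegen_error", responses = responses
  )
}

# error excerpt fed back into regeneration: bounded, tail-biased (shell
# errors usually trail), stderr before stdout
repair_excerpt <- function(finding, cap = 4000L) {
  tail_chars(finding$excerpt, cap)
}

#' Run the automatic code repair cycle for one step
#'
#' Executes the initial code; while the outcome is classified as an error
#' and repair attempts remain, the captured error excerpt is appended to
#' the code-generation prompt (previous code / observed error / fix it),
#' the code is regenerated and re-executed. Returns on the first success
#' or when the bound is exhausted -- exhaustion is a reported outcome,
#' not an exception. At most `max_repair_attempts + 1` executions ever
#' happen; `max_repair_attempts = 0` disables repair.
#'
#' @param backend A backend object.
#' @param ctx A [prompt_context()] for the step (sub-goal as
#'   `current_goal`).
#' @param step A `plan_step`.
#' @param initial A `code_block` from [generate_code()].
#' @param executor Function `(code_block) -> execution outcome`: either an
#'   `execution_result` (classified here via [detect_error()]) or a list
#'   with elements `result` (an `execution_result` or `NULL`) and
#'   `finding` (an `error_finding`, e.g. a denylist rejection).
#' @param max_repair_attempts Non-negative repair bound.
#' @param error_patterns Patterns for [detect_error()].
#' @param temperature,profile Decoding settings.
#' @param log Optional run log (internal).
#' @return A list with `success` (flag), `final` (last
#'   `execution_result` or `NULL`), and `attempts` (list of records with
#'   `attempt`, `code`, `result`, `error_excerpt`).
#' @export
repair_loop <- function(backend, ctx, step, initial, executor,
                        max_repair_attempts = 5L,
                        error_patterns = default_error_patterns(),
                        temperature = 0, profile = "transcript", log = NULL) {
  stopifnot(inherits(initial, "code_block"))
  if (!is_count(max_repair_attempts)) {
    contract_error("max_repair_attempts must be a non-negative integer")
  }
  attempts <- list()
  code <- initial
  for (attempt in seq_len(max_repair_attempts + 1L)) {
    code$attempt <- attempt
    outcome <- executor(code)
    if (inherits(outcome, "execution_result")) {
      result <- outcome
      finding <- detect_error(result, error_patterns)
    } else {
      result <- outcome$result
      finding <- outcome$finding
    }
    excerpt <- if (finding$is_error) repair_excerpt(finding) else ""
    attempts[[attempt]] <- list(attempt = attempt, code = code,
                                result = result, error_excerpt = excerpt)
    log_event(log, "repair_attempt",
              list(step = step$index, attempt = attempt,
                   is_error = finding$is_error, reason = finding$reason,
                   excerpt = excerpt))
    if (!finding$is_error) {
      return(list(success = TRUE, final = result, attempts = attempts))
    }
    if (attempt > max_repair_attempts) break
    prompt <- render_repair_prompt(ctx, step, code$shell_text, excerpt)
    log_event(log, "prompt", list(phase = "repair", step = step$index,
                                  attempt = attempt + 1L, text = prompt))
    resp <- complete(backend, backend_request(prompt, temperature = temperature,
                                              profile = profile))
    log_event(log, "backend_response",
              list(phase = "repair", step = step$index, attempt = attempt + 1L,
                   finish_state = resp$finish_state, text = resp$text))
    if (resp$finish_state != "complete") break
    new_text <- tryCatch(extract_code(resp$text),
                         agent_extraction_error = function(e) NULL)
    if (is.null(new_text)) break
    code <- code_block(step$index, new_text, attempt = attempt + 1L,
                       source_response = resp$text)
  }
  list(success = FALSE,
       final = attempts[[length(attempts)]]$result,
       attempts = attempts)
}
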