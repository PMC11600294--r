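## Language-model backend contract.
##
## Every backend answers `complete()` on a backend_request and returns a
## backend_response; model-side refusals and transport exhaustion are
## encoded in finish_state, never raised.  Three implementations:
##   * transcript_backend -- deterministic replay from a matcher->response
##     table; the only backend the test suite touches.
##   * chat_api_backend   -- thin adapter for an OpenAI-style chat HTTP API.
##   * local_command_backend -- thin adapter running a local instruct-model
##     command (prompt on stdin, completion on stdout).

#' Construct a backend request
#'
#' @param prompt Non-empty prompt text.
#' @param temperature Decoding temperature, `>= 0`.
#' @param max_output_tokens Positive cap on completion length.
#' @param profile Identifier of the backend profile handling the request.
#' @return A `backend_request`.
#' @export
backend_request <- function(prompt, temperature = 0,
                            max_output_tokens = 4096L,
                            profile = "transcript") {
  if (!is_nonempty_string(prompt)) contract_error("prompt must be non-empty")
  if (!is.numeric(temperature) || temperature < 0) {
    contract_error("temperature must be >= 0")
  }
  if (!is_count(max_output_tokens, min = 1L)) {
    contract_error("max_output_tokens must be a positive integer")
  }
  structure(
    list(prompt = prompt, temperature = as.numeric(temperature),
         max_output_tokens = as.integer(max_output_tokens),
         profile = profile),
    class = "backend_request"
  )
}

backend_response <- function(text, finish_state = c("complete", "truncated",
                                                    "refused", "backend_error"),
                             latency = 0) {
  finish_state <- match.arg(finish_state)
  if (finish_state == "complete" && !is_nonempty_string(text)) {
    contract_error("a complete response must carry non-empty text")
  }
  structure(list(text = text, finish_state = finish_state, latency = latency),
            class = "backend_response")
}

#' Request a completion from a backend
#'
#' @param backend A backend object (see [transcript_backend()],
#'   [chat_api_backend()], [local_command_backend()]).
#' @param request A [backend_request()].
#' @return A `backend_response` with fields `text`, `finish_state`
#'   (`complete` / `truncated` / `refused` / `backend_error`) and
#'   `latency` in seconds. Never raises for model-side refusals.
#' @export
complete <- function(backend, request) UseMethod("complete")

## Transcript backend ----------------------------------------------------

#' Construct a transcript entry
#'
#' @param matcher_kind How the prompt is matched: `"substring"` (fixed
#'   substring of the whitespace-normalized prompt), `"hash"` (FNV-1a
#'   32-bit hex digest of the whole normalized prompt) or `"exact"`.
#' @param matcher The pattern or digest.
#' @param response Completion text to replay.
#' @param max_uses Positive integer or `Inf` (unlimited). Limiting uses
#'   lets a transcript answer a repeated prompt differently on the next
#'   attempt, emulating regeneration under the repair loop.
#' @return A `transcript_entry`.
#' @export
transcript_entry <- function(matcher_kind = c("substring", "hash", "exact"),
                             matcher, response, max_uses = Inf) {
  matcher_kind <- match.arg(matcher_kind)
  if (!is_nonempty_string(matcher)) validation_error("matcher must be non-empty")
  if (!is_string(response)) validation_error("response must be a string")
  if (!(identical(max_uses, Inf) || is_count(max_uses, min = 1L))) {
    validation_error("max_uses must be a positive integer or Inf")
  }
  structure(list(matcher_kind = matcher_kind, matcher = matcher,
                 response = response, max_uses = as.numeric(max_uses)),
            class = "transcript_entry")
}

#' Load a transcript file
#'
#' A transcript is a JSON array of objects with fields `matcher_kind`,
#' `matcher`, `response` and optional `max_uses`.
#'
#' @param path Path to the JSON file.
#' @return A validated list of [transcript_entry()] objects.
#' @export
load_transcript <- function(path) {
  if (!file.exists(path)) io_error(sprintf("transcript not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(raw, function(e) {
    transcript_entry(
      matcher_kind = e$matcher_kind %||% "substring",
      matcher = e$matcher,
      response = e$response,
      max_uses = if (is.null(e$max_uses)) Inf else e$max_uses
    )
  })
  validate_transcript(entries)
  entries
}

validate_transcript <- function(entries) {
  if (!length(entries)) return(invisible(entries))
  keys <- vapply(entries, function(e) paste0(e$matcher_kind, "\r", e$matcher), "")
  if (anyDuplicated(keys)) {
    i <- which(duplicated(keys))[1]
    j <- which(keys == keys[i])[1]
    validation_error(sprintf(
      "ambiguous transcript: entries %d and %d share matcher '%s'",
      j, i, entries[[i]]$matcher))
  }
  invisible(entries)
}

#' Deterministic transcript-replay backend
#'
#' A pure test double for a language model: answers each prompt from a
#' prerecorded matcher-to-response table. Prompts are whitespace-normalized
#' and run-specific tokens (workspace paths, run ids) are substituted by
#' declared placeholders before matching, so transcripts survive temp
#' directories. Entries are tried in order; exhausted entries
#' (`max_uses`) are skipped, which is how a repair transcript returns
#' broken code on the first attempt and fixed code on the second.
#'
#' @param entries List of [transcript_entry()] objects, or a path to a
#'   transcript JSON file.
#' @param placeholders Named character vector: `c(WORKSPACE = "/tmp/x")`
#'   replaces occurrences of `/tmp/x` in a prompt with `{{WORKSPACE}}`
#'   before matching.
#' @return A `transcript_backend`.
#' @export
transcript_backend <- function(entries, placeholders = character(0)) {
  if (is.character(entries) && length(entries) == 1L) {
    entries <- load_transcript(entries)
  }
  validate_transcript(entries)
  env <- new.env(parent = emptyenv())
  env$entries <- entries
  env$uses <- integer(length(entries))
  env$placeholders <- placeholders
  structure(env, class = c("transcript_backend", "agent_backend"))
}

normalize_prompt <- function(prompt, placeholders = character(0)) {
  for (nm in names(placeholders)) {
    prompt <- gsub(placeholders[[nm]], paste0("{{", nm, "}}"), prompt,
                   fixed = TRUE)
  }
  normalize_ws(prompt)
}

#' @export
complete.transcript_backend <- function(backend, request) {
  stopifnot(inherits(request, "backend_request"))
  norm <- normalize_prompt(request$prompt, backend$placeholders)
  norm_hash <- fnv1a32(norm)
  for (i in seq_along(backend$entries)) {
    e <- backend$entries[[i]]
    if (backend$uses[i] >= e$max_uses) next
    hit <- switch(e$matcher_kind,
      substring = grepl(e$matcher, norm, fixed = TRUE),
      hash = identical(e$matcher, norm_hash),
      exact = identical(e$matcher, norm)
    )
    if (isTRUE(hit)) {
      backend$uses[i] <- backend$uses[i] + 1L
      return(backend_response(e$response, "complete", latency = 0))
    }
  }
  nearest <- nearest_matcher(norm, backend$entries)
  backend_response(
    paste0("transcript backend: no entry matches the prompt. ",
           "Nearest matcher: ", nearest),
    "backend_error", latency = 0
  )
}

nearest_matcher <- function(norm, entries) {
  if (!length(entries)) return("(transcript is empty)")
  d <- vapply(entries, function(e) {
    utils::adist(e$matcher, norm, partial = TRUE)[1, 1]
  }, 1)
  entries[[which.min(d)]]$matcher
}

## Live adapters (thin optional shims; never used by the test suite) -----

#' Online chat-API backend adapter
#'
#' Thin adapter for an OpenAI-style `/chat/completions` endpoint. The API
#' key is read from an environment variable at call time and never
#' stored. Transient transport failures are retried with exponential
#' backoff; exhaustion yields a `backend_error` response rather than an
#' exception.
#'
#' @param model Model identifier, e.g. `"gpt-4"`.
#' @param base_url API base URL.
#' @param api_key_env Name of the environment variable holding the key.
#' @param max_retries Transport retry count.
#' @return A `chat_api_backend`.
#' @export
chat_api_backend <- function(model = "gpt-4",
                             base_url = "https://api.openai.com/v1",
                             api_key_env = "OPENAI_API_KEY",
                             max_retries = 3L) {
  structure(list(model = model, base_url = base_url,
                 api_key_env = api_key_env, max_retries = max_retries),
            class = c("chat_api_backend", "agent_backend"))
}

#' @export
complete.chat_api_backend <- function(backend, request) {
  stopifnot(inherits(request, "backend_request"))
  if (!requireNamespace("curl", quietly = TRUE)) {
    config_error("the chat-API backend requires the 'curl' package")
  }
  key <- Sys.getenv(backend$api_key_env, "")
  if (!nzchar(key)) {
    config_error(sprintf("environment variable %s is not set",
                         backend$api_key_env))
  }
  body <- jsonlite::toJSON(list(
    model = backend$model,
    messages = list(list(role = "user", content = request$prompt)),
    temperature = request$temperature,
    max_tokens = request$max_output_tokens
  ), auto_unbox = TRUE)
  t0 <- Sys.time()
  for (attempt in seq_len(backend$max_retries)) {
    res <- tryCatch({
      h <- curl::new_handle()
      curl::handle_setheaders(h,
        "Content-Type" = "application/json",
        "Authorization" = paste("Bearer", key))
      curl::handle_setopt(h, postfields = body)
      curl::curl_fetch_memory(paste0(backend$base_url, "/chat/completions"), h)
    }, error = function(e) e)
    if (!inherits(res, "error") && res$status_code < 500) {
      lat <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      parsed <- jsonlite::fromJSON(rawToChar(res$content),
                                   simplifyVector = FALSE)
      if (res$status_code != 200) {
        return(backend_response(paste("API error:", rawToChar(res$content)),
                                "backend_error", lat))
      }
      choice <- parsed$choices[[1]]
      state <- switch(choice$finish_reason %||% "stop",
                      stop = "complete", length = "truncated",
                      content_filter = "refused", "complete")
      return(backend_response(choice$message$content %||% "", state, lat))
    }
    Sys.sleep(2^(attempt - 1))
  }
  backend_response("transport retries exhausted", "backend_error",
                   as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Local instruct-model backend adapter
#'
#' Runs a local command (for example a llama.cpp-style CLI wrapping an
#' instruction-tuned model) with the prompt on standard input and reads
#' the completion from standard output.
#'
#' @param command Executable to run.
#' @param args Character vector of extra arguments.
#' @return A `local_command_backend`.
#' @export
local_command_backend <- function(command, args = character(0)) {
  structure(list(command = command, args = args),
            class = c("local_command_backend", "agent_backend"))
}

#' @export
complete.local_command_backend <- function(backend, request) {
  stopifnot(inherits(request, "backend_request"))
  if (!nzchar(Sys.which(backend$command))) {
    config_error(sprintf("backend command not found: %s", backend$command))
  }
  t0 <- Sys.time()
  out <- tryCatch(
    system2(backend$command, backend$args, input = request$prompt,
            stdout = TRUE, stderr = FALSE),
    error = function(e) e
  )
  lat <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (inherits(out, "error")) {
    return(backend_response(conditionMessage(out), "backend_error", lat))
  }
  status <- attr(out, "status") %||% 0L
  text <- paste(out, collapse = "\n")
  if (status != 0) return(backend_response(text, "backend_error", lat))
  backend_response(text, "complete", lat)
}

## Profile resolution ----------------------------------------------------

#' Resolve a backend profile string to a backend object
#'
#' Profiles: `"transcript:<path>"` (replay the given transcript file),
#' `"chat_api"` / `"chat_api:<model>"` (online chat API) and
#' `"local:<command>"` (local instruct-model command).
#'
#' @param profile Profile identifier from the run configuration.
#' @param placeholders Placeholder map for transcript normalization.
#' @return A backend object.
#' @export
resolve_backend <- function(profile, placeholders = character(0)) {
  if (!is_nonempty_string(profile)) config_error("backend profile must be a string")
  parts <- strsplit(profile, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  arg <- if (length(parts) > 1L) paste(parts[-1], collapse = ":") else NULL
  switch(kind,
    transcript = {
      if (is.null(arg)) config_error("profile 'transcript' needs a path: transcript:<file>")
      transcript_backend(arg, placeholders = placeholders)
    },
    chat_api = if (is.null(arg)) chat_api_backend() else chat_api_backend(model = arg),
    local = {
      if (is.null(arg)) config_error("profile 'local' needs a command: local:<cmd>")
      local_command_backend(arg)
    },
    config_error(sprintf("unknown backend profile: %s", profile))
  )
}
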