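## Planning phase: obtain an ordered analysis plan from the backend and
## parse it into software-annotated steps.

#' Known bioinformatics tool lexicon
#'
#' Seed vocabulary for software-name recognition in plan text, drawn from
#' the tools the bundled 40-case benchmark registry records (aligners,
#' trimmers, peak callers, quantifiers, differential-expression and
#' single-cell frameworks, and the like). Extensible via `extra`.
#'
#' @param extra Additional tool names to recognize.
#' @return Character vector of tool names.
#' @export
known_tools <- function(extra = character(0)) {
  c(
    "FastQC", "Trimmomatic", "SPAdes", "QUAST", "BWA", "Samtools", "GATK",
    "ensembl-vep", "manta", "pindel", "SnpEff", "Trim Galore", "Bowtie 2",
    "Bowtie2", "Bowtie", "MACS2", "MACS", "BEDTools", "IGV", "HOMER", "MEME",
    "DESeq2", "g:Profiler", "gprofileR", "Bismark", "Cutadapt", "GREAT",
    "canu", "Minimap2", "Racon", "Flye", "Medaka", "Bandage", "trf",
    "FALCON", "Quiver", "MUMmer", "HISAT2", "Hisat2", "HTSeq", "htseq",
    "htseq-count", "fusioncatcher", "gffcompare", "StringTie",
    "featureCounts", "subread", "rMATs", "DaPars", "ballgown", "CIRI2",
    "CIRIQuant", "edgeR", "miRDeep2", "CAGEr", "cufflinks", "Piranha",
    "RiboTaper", "Cell Ranger", "Seurat", "Scanpy", "Squidpy", "AnnData",
    "Tangram", "proteowizard", "OpenMS", "pymzml", "STAR", "Salmon",
    "Kallisto", "gunzip", "Bcftools", "Picard",
    extra
  )
}

plan_step <- function(index, description, software = character(0),
                      inputs_mentioned = character(0)) {
  if (!is_nonempty_string(description)) {
    validation_error("plan step description must be non-empty")
  }
  structure(list(index = as.integer(index), description = description,
                 software = software, inputs_mentioned = inputs_mentioned),
            class = "plan_step")
}

new_plan <- function(steps, raw_text) {
  if (!length(steps)) validation_error("a plan must contain at least one step")
  idx <- vapply(steps, function(s) s$index, 1L)
  if (!identical(idx, seq_along(steps))) {
    validation_error("plan step indices must be consecutive from 1")
  }
  structure(list(steps = steps, raw_text = raw_text), class = "analysis_plan")
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat("<analysis_plan> ", length(x$steps), " step(s)\n", sep = "")
  for (s in x$steps) {
    tools <- if (length(s$software)) paste0(" [", paste(s$software, collapse = ", "), "]") else ""
    desc <- s$description
    if (nchar(desc) > 70) desc <- paste0(substr(desc, 1, 67), "...")
    cat(sprintf("  %d. %s%s\n", s$index, desc, tools))
  }
  invisible(x)
}

#' Parse planner output into an ordered plan
#'
#' Plans arrive either as explicitly numbered lists (`1. ...`) or as
#' prose paragraphs chained with ordinal connectives (First, Next, Then,
#' After that, Finally). Both splitters run; the one recognizing more
#' steps wins (ties go to the numbered parse, the more explicit style).
#' Software names are extracted per step from double-quoted tokens plus a
#' case-insensitive match against [known_tools()]; file paths are
#' extracted by pattern.
#'
#' @param text Raw planner output.
#' @param tools Tool lexicon used for software recognition.
#' @return An `analysis_plan` whose `raw_text` is `text`, unmodified.
#' @export
parse_plan <- function(text, tools = known_tools()) {
  if (!is_nonempty_string(text)) parse_error("empty plan text")
  numbered <- split_numbered(text)
  ordinal <- split_ordinal(text)
  pieces <- if (length(ordinal) > length(numbered)) ordinal else numbered
  if (!length(pieces)) {
    parse_error(paste0("no plan steps recognized in text: ",
                       tail_chars(normalize_ws(text), 200)))
  }
  steps <- lapply(seq_along(pieces), function(i) {
    plan_step(i, pieces[i],
              software = extract_software(pieces[i], tools),
              inputs_mentioned = extract_paths(pieces[i]))
  })
  new_plan(steps, text)
}

# "1. ..." / "2) ..." line-anchored numbering
split_numbered <- function(text) {
  m <- gregexpr("(?m)^[ \t]*\\d+[.)][ \t]+", text, perl = TRUE)[[1]]
  if (m[1] < 0) return(character(0))
  starts <- as.integer(m)
  ends <- c(starts[-1] - 1L, nchar(text))
  pieces <- substring(text, starts, ends)
  pieces <- sub("^[ \t]*\\d+[.)][ \t]+", "", pieces)
  trimws(pieces[nzchar(trimws(pieces))])
}

# ordinal connectives at sentence starts; quotes may close the previous
# sentence and prose sometimes omits the space after the period
split_ordinal <- function(text) {
  pat <- paste0(
    "(?:^|(?<=[.!?])|(?<=[.!?] )|(?<=[.!?]”)|(?<=[.!?]” )|",
    "(?<=[.!?]\")|(?<=[.!?]\" ))",
    "(?:First|Second|Third|Fourth|Fifth|Sixth|Next|Then|After that|",
    "Afterwards|Finally|Lastly)\\b[, ]"
  )
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] < 0) return(character(0))
  starts <- as.integer(m)
  ends <- c(starts[-1] - 1L, nchar(text))
  trimws(substring(text, starts, ends))
}

extract_software <- function(step_text, tools) {
  found <- character(0)
  pos <- integer(0)
  # double-quoted tokens (straight or typographic), kept even if unknown;
  # quoted file paths are not software
  m <- gregexpr("[\"“]([^\"“”\n]{1,60})[\"”]",
                step_text, perl = TRUE)[[1]]
  if (m[1] > 0) {
    toks <- regmatches(step_text, list(m))[[1]]
    toks <- gsub("^[\"“]|[\"”]$", "", toks)
    keep <- !grepl("/", toks, fixed = TRUE)
    found <- c(found, toks[keep])
    pos <- c(pos, as.integer(m)[keep])
  }
  for (tool in tools) {
    hit <- regexpr(paste0("(?<![\\w-])", escape_regex(tool), "(?![\\w-])"),
                   step_text, perl = TRUE, ignore.case = TRUE)
    if (hit > 0) {
      found <- c(found, tool)
      pos <- c(pos, as.integer(hit))
    }
  }
  ord <- order(pos)
  found <- found[ord]
  found[!duplicated(tolower(found))]
}

extract_paths <- function(step_text) {
  m <- gregexpr("(?:\\.{1,2})?/[\\w.\\-]+(?:/[\\w.\\-]+)*", step_text,
                perl = TRUE)[[1]]
  if (m[1] < 0) return(character(0))
  paths <- regmatches(step_text, list(m))[[1]]
  unique(paths)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.#:<>=!-])", "\\\\\\1", x, perl = TRUE)

#' Obtain a plan from the backend
#'
#' Renders the planning prompt, asks the backend, and parses the response
#' with [parse_plan()]. On a parse failure (or a non-`complete` backend
#' response) the backend is re-asked with the diagnostic appended, up to
#' `max_attempts` additional times.
#'
#' @param backend A backend object.
#' @param ctx A [prompt_context()] whose `current_goal` is the global
#'   objective.
#' @param max_attempts Bound on re-asks after the first failure.
#' @param temperature,profile Decoding settings passed to the backend.
#' @param extra Optional instruction appended to the prompt (used by the
#'   orchestrator to re-propose after blacklist violations).
#' @param log Optional run log (internal).
#' @return An `analysis_plan`.
#' @export
propose_plan <- function(backend, ctx, max_attempts = 5L, temperature = 0,
                         profile = "transcript", extra = NULL, log = NULL) {
  base_prompt <- render_planning_prompt(ctx)
  if (!is.null(extra)) base_prompt <- paste0(base_prompt, "\n\n", extra)
  responses <- list()
  diagnostic <- NULL
  for (attempt in seq_len(max_attempts + 1L)) {
    prompt <- base_prompt
    if (!is.null(diagnostic)) {
      prompt <- paste0(
        base_prompt,
        "\n\nYour previous response could not be used as a plan: ",
        diagnostic,
        "\nRespond again with an ordered, numbered step list."
      )
    }
    log_event(log, "prompt", list(phase = "planning", attempt = attempt,
                                  text = prompt))
    resp <- complete(backend, backend_request(prompt, temperature = temperature,
                                              profile = profile))
    log_event(log, "backend_response",
              list(phase = "planning", attempt = attempt,
                   finish_state = resp$finish_state, text = resp$text))
    responses[[attempt]] <- resp
    if (resp$finish_state != "complete") {
      diagnostic <- paste0("backend returned state '", resp$finish_state, "'")
      next
    }
    plan <- tryCatch(parse_plan(resp$text), agent_parse_error = function(e) e)
    if (inherits(plan, "analysis_plan")) return(plan)
    diagnostic <- conditionMessage(plan)
  }
  agent_abort(
    sprintf("planning failed after %d attempt(s): %s",
            max_attempts + 1L, diagnostic),
    "agent_planning_error",
    responses = responses
  )
}

#' Check a plan against the software blacklist
#'
#' @param plan An `analysis_plan`.
#' @param blacklist Character vector of prohibited software names.
#' @return Data frame with columns `step_index` and `software`, one row
#'   per case-insensitive match; zero rows when the plan is clean. The
#'   orchestrator treats any row as a plan rejection and re-proposes.
#' @export
check_blacklist <- function(plan, blacklist) {
  stopifnot(inherits(plan, "analysis_plan"))
  out <- data.frame(step_index = integer(0), software = character(0),
                    stringsAsFactors = FALSE)
  if (!length(blacklist)) return(out)
  folded <- tolower(blacklist)
  for (s in plan$steps) {
    bad <- s$software[tolower(s$software) %in% folded]
    if (length(bad)) {
      out <- rbind(out, data.frame(step_index = s$index, software = bad,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
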