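## The bundled 40-case benchmark registry and its stage-wise summarizer.

OMICS_TYPES <- c("genomics", "transcriptomics", "proteomics", "metabolomics")

#' Load the benchmark case registry
#'
#' Reads the bundled (or a user-supplied) registry of benchmark cases:
#' one row per case with expert-assessed pass/fail outcomes for the
#' three stages (propose plan, generate code, execute code), in both the
#' no-repair and with-repair variants, plus the tools chosen and the
#' code-generation time. Validation enforces the stage-implication chain
#' (execute pass implies codegen pass implies plan pass, per variant)
#' and that a failure reason is present exactly when some no-repair
#' stage failed.
#'
#' @param path CSV path; defaults to the registry shipped with the
#'   package.
#' @return A data frame of class `case_registry`.
#' @export
load_case_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "case_registry.csv", package = "omicsagent")
  }
  if (!file.exists(path)) io_error(sprintf("registry file not found: %s", path))
  reg <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("case_id", "class", "task", "omics",
              "plan_noacr", "codegen_noacr", "execute_noacr",
              "plan_acr", "codegen_acr", "execute_acr",
              "failure_reason", "tools", "time_min")
  missing <- setdiff(needed, names(reg))
  if (length(missing)) {
    validation_error(sprintf("registry lacks column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  reg$time_min <- as.integer(reg$time_min)
  if (anyDuplicated(reg$case_id)) {
    validation_error(sprintf("duplicate case_id: %s",
                             reg$case_id[duplicated(reg$case_id)][1]))
  }
  stage_cols <- c("plan_noacr", "codegen_noacr", "execute_noacr",
                  "plan_acr", "codegen_acr", "execute_acr")
  for (col in stage_cols) {
    bad <- !reg[[col]] %in% c("pass", "fail")
    if (any(bad)) {
      validation_error(sprintf("case %s: %s must be pass or fail",
                               reg$case_id[bad][1], col))
    }
  }
  bad <- !reg$omics %in% OMICS_TYPES
  if (any(bad)) {
    validation_error(sprintf("case %s: unknown omics type '%s'",
                             reg$case_id[bad][1], reg$omics[bad][1]))
  }
  for (variant in c("noacr", "acr")) {
    p <- reg[[paste0("plan_", variant)]] == "pass"
    c_ <- reg[[paste0("codegen_", variant)]] == "pass"
    e <- reg[[paste0("execute_", variant)]] == "pass"
    bad <- (e & !c_) | (c_ & !p)
    if (any(bad)) {
      validation_error(sprintf(
        "case %s violates the stage-implication chain (execute => codegen => plan) in the %s variant",
        reg$case_id[bad][1], variant))
    }
  }
  some_fail <- reg$plan_noacr == "fail" | reg$codegen_noacr == "fail" |
    reg$execute_noacr == "fail"
  has_reason <- nzchar(trimws(reg$failure_reason))
  bad <- xor(some_fail, has_reason)
  if (any(bad)) {
    validation_error(sprintf(
      "case %s: failure_reason must be non-empty iff some stage failed",
      reg$case_id[bad][1]))
  }
  class(reg) <- c("case_registry", "data.frame")
  reg
}

#' Summarize stage-wise success rates over a case registry
#'
#' Counts, per stage (plan, codegen, execute), how many cases passed in
#' the chosen variant and expresses each as a percentage of the total to
#' one decimal, together with per-omics-type case counts.
#'
#' @param records A `case_registry` (or compatible data frame).
#' @param variant `"no_acr"` (repair disabled) or `"with_acr"`.
#' @return An `evaluation_summary` with fields `total`, `counts`,
#'   `percentages`, `per_omics`, `variant`.
#' @export
summarize_evaluation <- function(records, variant = c("no_acr", "with_acr")) {
  variant <- match.arg(variant)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    contract_error("records must be a non-empty registry data frame")
  }
  suffix <- if (variant == "no_acr") "noacr" else "acr"
  total <- nrow(records)
  counts <- vapply(c("plan", "codegen", "execute"), function(stage) {
    sum(records[[paste0(stage, "_", suffix)]] == "pass")
  }, 1L)
  percentages <- round(100 * counts / total, 1)
  per_omics <- table(factor(records$omics, levels = OMICS_TYPES))
  structure(
    list(total = total, counts = as.list(counts),
         percentages = as.list(percentages),
         per_omics = as.list(per_omics), variant = variant),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary> variant=", x$variant, ", ", x$total,
      " cases\n", sep = "")
  for (stage in c("plan", "codegen", "execute")) {
    cat(sprintf("  %-8s %2d/%d passed (%.1f%%)\n", stage,
                x$counts[[stage]], x$total, x$percentages[[stage]]))
  }
  cat("  omics: ",
      paste(sprintf("%s=%d", names(x$per_omics), unlist(x$per_omics)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
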