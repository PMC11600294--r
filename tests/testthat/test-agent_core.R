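# inline three-step scenario whose second step can be made unrepairable
three_step_config <- function(dir) {
  dir.create(file.path(dir, "payload", "data"), recursive = TRUE)
  writeLines(c("alpha", "beta"), file.path(dir, "payload", "data", "input.txt"))
  cfg <- parse_config(paste(
    "data:",
    "  - ./data/input.txt: plain text records",
    "goal: process the records end to end",
    "output_dir: runs",
    sep = "\n"), base_dir = dir)
  cfg
}

# stage the payload data into the fresh workspace root
three_step_setup <- function(dir) {
  function(ws) {
    file.copy(file.path(dir, "payload", "data"), ws$root, recursive = TRUE)
  }
}

three_step_backend <- function(repairable) {
  steps <- c("Count the records in ./data/input.txt.",
             "Transform the records into ./output/stage2.txt.",
             "Copy the transformed records to ./output/final.txt.")
  plan_text <- paste(sprintf("%d. %s", 1:3, steps), collapse = "\n")
  entries <- list(
    transcript_entry("substring",
                     "Respond with an ordered, numbered step-by-step analysis plan",
                     plan_text),
    transcript_entry("substring", omicsagent:::goal_matcher(steps[1]),
                     "```bash\nwc -l ./data/input.txt\n```"),
    transcript_entry("substring", omicsagent:::goal_matcher(steps[2]),
                     "```bash\nmkdir -p output\ncat ./data/absent.txt > ./output/stage2.txt\n```",
                     max_uses = if (repairable) 1 else Inf),
    transcript_entry("substring", omicsagent:::goal_matcher(steps[3]),
                     "```bash\ncp ./output/stage2.txt ./output/final.txt\n```")
  )
  if (repairable) {
    entries <- append(entries, list(transcript_entry(
      "substring", "No such file or directory",
      "```bash\nmkdir -p output\ntr a-z A-Z < ./data/input.txt > ./output/stage2.txt\n```")))
  }
  transcript_backend(entries)
}

test_that("a repairable failure yields an end-to-end run with one extra attempt", {
  dir <- tempfile("agent")
  cfg <- three_step_config(dir)
  rep <- run_agent(cfg, backend = three_step_backend(TRUE), run_id = "ok",
                   workspace_setup = three_step_setup(dir))
  expect_true(rep$stage_flags$plan_ok)
  expect_true(rep$stage_flags$all_codegen_ok)
  expect_true(rep$stage_flags$end_to_end_ok)
  expect_identical(rep$step_outcomes$status, rep("success", 3))
  expect_identical(rep$step_outcomes$attempts, c(1L, 2L, 1L))
  expect_true(file.exists(file.path(dir, "runs", "ok", "output", "final.txt")))
  unlink(dir, recursive = TRUE)
})

test_that("an unrepairable step fails after the bound and later steps are skipped", {
  dir <- tempfile("agent")
  cfg <- three_step_config(dir)
  cfg$max_repair_attempts <- 2L
  rep <- run_agent(cfg, backend = three_step_backend(FALSE), run_id = "bad",
                   workspace_setup = three_step_setup(dir))
  expect_true(rep$stage_flags$plan_ok)
  expect_false(rep$stage_flags$end_to_end_ok)
  expect_identical(rep$step_outcomes$status, c("success", "failed", "skipped"))
  expect_identical(rep$step_outcomes$attempts[2], 3L)  # 1 + 2 repairs
  # fail-stop: the skipped step was never executed
  expect_false(any(grepl("^step3_attempt",
                         list.files(file.path(dir, "runs", "bad", "scripts")))))
  # stage implication chain
  f <- rep$stage_flags
  expect_true(!f$end_to_end_ok || f$all_codegen_ok)
  expect_true(!f$all_codegen_ok || f$plan_ok)
  unlink(dir, recursive = TRUE)
})

test_that("planning failure produces a report with plan_ok=false and no steps", {
  dir <- tempfile("agent")
  cfg <- three_step_config(dir)
  cfg$max_repair_attempts <- 1L
  prose_backend <- transcript_backend(list(transcript_entry(
    "substring", "<<CURRENT_GOAL>>", "no plan, just words of encouragement")))
  rep <- run_agent(cfg, backend = prose_backend, run_id = "noplan",
                   workspace_setup = three_step_setup(dir))
  expect_false(rep$stage_flags$plan_ok)
  expect_false(rep$stage_flags$all_codegen_ok)
  expect_false(rep$stage_flags$end_to_end_ok)
  expect_identical(nrow(rep$step_outcomes), 0L)
  unlink(dir, recursive = TRUE)
})

test_that("blacklisted plans are rejected and the violation drives re-proposal", {
  dir <- tempfile("agent")
  cfg <- three_step_config(dir)
  cfg$blacklist <- "ForbiddenTool"
  cfg$max_repair_attempts <- 1L
  bad_plan <- paste(
    '1. Use the "ForbiddenTool" software to count the records.',
    "2. Copy the result somewhere.", sep = "\n")
  good_steps <- c("Count the records with wc.", "Report completion.")
  good_plan <- paste(sprintf("%d. %s", 1:2, good_steps), collapse = "\n")
  be <- transcript_backend(list(
    transcript_entry("substring",
                     "Respond with an ordered, numbered step-by-step analysis plan",
                     bad_plan, max_uses = 1),
    transcript_entry("substring", "avoids every blacklisted tool", good_plan),
    transcript_entry("substring", omicsagent:::goal_matcher(good_steps[1]),
                     "```bash\nwc -l ./data/input.txt\n```"),
    transcript_entry("substring", omicsagent:::goal_matcher(good_steps[2]),
                     "```bash\necho complete\n```")
  ))
  rep <- run_agent(cfg, backend = be, run_id = "bl",
                   workspace_setup = three_step_setup(dir))
  expect_true(rep$stage_flags$end_to_end_ok)
  # the accepted plan contains no blacklist violation
  expect_identical(nrow(check_blacklist(rep$plan, cfg$blacklist)), 0L)
  unlink(dir, recursive = TRUE)
})

test_that("memory grows only on success and replay reconstructs the report", {
  dir <- tempfile("agent")
  cfg <- three_step_config(dir)
  rep <- run_agent(cfg, backend = three_step_backend(TRUE), run_id = "mem",
                   workspace_setup = three_step_setup(dir))
  log_path <- file.path(dir, "runs", "mem", "logs", "run.jsonl")
  events <- omicsagent:::read_log_events(log_path)
  kinds <- vapply(events, function(e) e$event, "")
  # one success record per successful step, none for failures
  expect_identical(sum(kinds == "step_success"),
                   sum(rep$step_outcomes$status == "success"))
  # every backend response and every execution appears in the log
  expect_gte(sum(kinds == "backend_response"), 5)
  expect_identical(sum(kinds == "execution"), sum(rep$step_outcomes$attempts))
  # the last codegen prompt's history summary lists previously completed tasks
  prompts <- Filter(function(e) identical(e$event, "prompt"), events)
  last_prompt <- prompts[[length(prompts)]]$payload$text
  hist <- extract_prompt_slots(last_prompt)$history_summary
  expect_match(hist, "successfully completed the task", fixed = TRUE)

  # replay: no re-execution, identical report
  replayed <- replay_run(file.path(dir, "runs", "mem"))
  expect_identical(omicsagent:::report_to_list(replayed),
                   omicsagent:::report_to_list(rep))
  unlink(dir, recursive = TRUE)
})

test_that("identical fixture and seed reproduce the run report byte for byte", {
  with_fixture("rnaseq_deg", 13, function(dir) {
    r1 <- run_fixture_case(dir, run_id = "a")
    r2 <- run_fixture_case(dir, run_id = "b")
    expect_identical(canonical_report(r1), canonical_report(r2))
  })
})
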