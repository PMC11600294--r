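plan_record <- function(tasks = c("trim adapters", "align reads",
                                  "convert to BAM", "count reads",
                                  "test differential expression")) {
  history_record("input_and_plan", data_entries = demo_entries(),
                 global_goal = "identify differentially expressed genes",
                 plan_tasks = tasks)
}

task_record <- function(task = "trim adapters",
                        code = "trimmomatic SE -phred33 in.fastq.gz out.fastq.gz") {
  history_record("task_completed", task = task, code = code)
}

test_that("memory renders the two fixed sentence templates with slots filled", {
  txt <- summarize_history(list(plan_record(), task_record()))
  expect_match(txt, paste0(
    "First, you provided input in the format 'file path: file description' ",
    "in a list: "), fixed = TRUE)
  expect_match(txt, "You devised a detailed plan to accomplish your overarching objective.",
               fixed = TRUE)
  expect_match(txt, "Your overarching goal is identify differentially expressed genes.",
               fixed = TRUE)
  expect_match(txt, "Your plan involves ", fixed = TRUE)
  expect_match(txt, paste0(
    "Then, you successfully completed the task: trim adapters with the ",
    "corresponding code: trimmomatic SE -phred33 in.fastq.gz out.fastq.gz."),
    fixed = TRUE)
  expect_match(txt, "./data/SRR1374921.fastq.gz: single-end reads in LoGlu group",
               fixed = TRUE)
  expect_identical(summarize_history(list()), "")
})

test_that("history ordering contract is enforced", {
  expect_error(summarize_history(list(task_record())),
               class = "agent_contract_error")
  expect_error(summarize_history(list(plan_record(), plan_record())),
               class = "agent_contract_error")
})

test_that("budget elision keeps the plan sentence and the newest tasks", {
  records <- c(list(plan_record()),
               lapply(1:50, function(i) {
                 task_record(sprintf("task number %d", i),
                             sprintf("echo step_%d", i))
               }))
  full <- summarize_history(records)
  budget <- 300L  # ~1200 chars; far below the full text
  out <- summarize_history(records, token_budget = budget)
  expect_lt(nchar(out), nchar(full))
  expect_match(out, "First, you provided input", fixed = TRUE)
  expect_match(out, "task number 50", fixed = TRUE)
  expect_match(out, "earlier completed tasks elided", fixed = TRUE)

  # independent oracle: drop oldest task sentences one at a time until the
  # assembled text fits the character budget, never dropping the last one
  plan_sentence <- summarize_history(records[1])
  task_sentences <- vapply(2:51, function(i) summarize_history(records[c(1, i)]), "")
  task_sentences <- substring(task_sentences, nchar(plan_sentence) + 2L)
  drop <- 0L
  repeat {
    kept <- task_sentences[(drop + 1L):50]
    marker <- if (drop > 0)
      sprintf("[%d earlier completed tasks elided.]", drop) else NULL
    txt <- paste(c(plan_sentence, marker, kept), collapse = " ")
    if (nchar(txt) <= 4L * budget || length(kept) == 1L) break
    drop <- drop + 1L
  }
  expect_identical(out, txt)
})

test_that("memory grows by suffix extension while under budget", {
  records <- list(plan_record())
  prev <- summarize_history(records)
  for (i in 1:5) {
    records <- c(records, list(task_record(sprintf("t%d", i), sprintf("c%d", i))))
    cur <- summarize_history(records)
    expect_true(startsWith(cur, prev))
    prev <- cur
  }
})

test_that("rendered prompts contain every slot value and degenerate markers", {
  ctx <- demo_ctx(blacklist = c("DaPars", "CIRI2"))
  p <- render_planning_prompt(ctx)
  expect_match(p, "./data/SRR1374921.fastq.gz", fixed = TRUE)
  expect_match(p, "identify differentially expressed genes", fixed = TRUE)
  for (b in ctx$blacklist) {
    expect_identical(
      lengths(regmatches(p, gregexpr(b, p, fixed = TRUE))), 1L)
  }
  # empty blacklist renders the explicit none marker
  p0 <- render_planning_prompt(demo_ctx())
  expect_match(p0, "<<BLACKLIST>>\nnone\n<</BLACKLIST>>", fixed = TRUE)
  # empty history renders the explicit no-prior-actions marker
  expect_match(p0, "No prior actions.", fixed = TRUE)
  # determinism: identical context, identical bytes
  expect_identical(render_planning_prompt(ctx), p)
})

test_that("codegen prompt carries sub-goal, software and history", {
  step <- omicsagent:::plan_step(
    1L, 'use the "Trimmomatic" software to trim adapters',
    software = "Trimmomatic")
  ctx <- demo_ctx(goal = step$description,
                  history = "Then, you successfully completed the task: x with the corresponding code: y.")
  p <- render_codegen_prompt(ctx, step)
  expect_match(p, "Trimmomatic", fixed = TRUE)
  expect_match(p, "successfully completed the task: x", fixed = TRUE)
  expect_match(p, "exactly one fenced shell code block", fixed = TRUE)
  # contract: ctx goal must equal the step description
  expect_error(render_codegen_prompt(demo_ctx(goal = "something else"), step),
               class = "agent_contract_error")
})

test_that("slot extraction inverts rendering, including hostile values", {
  # values carrying the template's own delimiters must round-trip
  ctx <- prompt_context(
    blacklist = c("evil<<tool>>", "other%tool"),
    data_entries = data.frame(
      path = c("./data/x<<y.txt", "./data/z.txt"),
      description = c("desc with <</CURRENT_GOAL>> inside", "plain"),
      stringsAsFactors = FALSE),
    current_goal = "goal with %3C marker and <<DATA_LIST>>",
    history_summary = "history <<HISTORY_SUMMARY>> %25 text")
  for (render in list(render_planning_prompt,
                      function(c) render_codegen_prompt(
                        c, omicsagent:::plan_step(1L, c$current_goal)))) {
    s <- extract_prompt_slots(render(ctx))
    expect_identical(s$blacklist, ctx$blacklist)
    expect_identical(s$data_entries, ctx$data_entries)
    expect_identical(s$current_goal, ctx$current_goal)
    expect_identical(s$history_summary, ctx$history_summary)
  }

  # randomized contexts
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:4, 1)
    ctx <- prompt_context(
      blacklist = if (i %% 3 == 0) character(0) else
        vapply(seq_len(sample(1:3, 1)), function(j) rand_string(8), ""),
      data_entries = data.frame(
        path = vapply(seq_len(n), function(j)
          paste0("./d/", rand_string(6, pool = c(letters, "<", ">", "%"))), ""),
        description = vapply(seq_len(n), function(j) rand_string(20), ""),
        stringsAsFactors = FALSE),
      current_goal = rand_string(30),
      history_summary = if (i %% 4 == 0) "" else rand_string(60))
    s <- extract_prompt_slots(render_planning_prompt(ctx))
    expect_identical(s$blacklist, ctx$blacklist)
    expect_identical(s$data_entries, ctx$data_entries)
    expect_identical(s$current_goal, ctx$current_goal)
    expect_identical(s$history_summary, ctx$history_summary)
  }
})
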