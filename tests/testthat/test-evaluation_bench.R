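test_that("the bundled registry loads with the documented case facts", {
  reg <- load_case_registry()
  expect_identical(nrow(reg), 40L)
  r24 <- reg[reg$case_id == "2.4", ]
  expect_identical(r24$execute_noacr, "fail")
  expect_match(r24$failure_reason, "configuration file", fixed = TRUE)
  r101 <- reg[reg$case_id == "10.1", ]
  expect_true(grepl("HISAT2", r101$tools) && grepl("DESeq2", r101$tools))
  expect_identical(unlist(r101[c("plan_noacr", "codegen_noacr", "execute_noacr")],
                          use.names = FALSE), rep("pass", 3))
})

test_that("registry validation rejects stage-implication violations", {
  reg <- load_case_registry()
  tmp <- tempfile(fileext = ".csv")
  bad <- reg
  bad$codegen_noacr[bad$case_id == "10.1"] <- "fail"  # execute still pass
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_case_registry(tmp), "10.1",
               class = "agent_validation_error")

  bad2 <- reg
  bad2$failure_reason[bad2$case_id == "1.1"] <- "spurious reason"
  utils::write.csv(bad2, tmp, row.names = FALSE)
  expect_error(load_case_registry(tmp), "1.1",
               class = "agent_validation_error")
  unlink(tmp)
})

test_that("stage-wise summaries reproduce the recorded pass counts", {
  reg <- load_case_registry()
  s <- summarize_evaluation(reg, "no_acr")
  expect_identical(s$counts, list(plan = 36L, codegen = 33L, execute = 26L))
  expect_identical(s$percentages, list(plan = 90, codegen = 82.5, execute = 65))
  sa <- summarize_evaluation(reg, "with_acr")
  expect_identical(sa$counts$codegen, 35L)
  expect_identical(sa$counts$execute, 35L)
  expect_identical(sa$percentages$codegen, 87.5)
  expect_identical(sa$percentages$execute, 87.5)
  expect_identical(s$per_omics,
                   list(genomics = 15L, transcriptomics = 23L,
                        proteomics = 1L, metabolomics = 1L))

  single <- reg[reg$case_id == "1.1", ]
  s1 <- summarize_evaluation(single, "no_acr")
  expect_identical(s1$percentages, list(plan = 100, codegen = 100, execute = 100))
  expect_error(summarize_evaluation(reg[0, ], "no_acr"),
               class = "agent_contract_error")
})

test_that("summaries match brute-force counting on random synthetic registries", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(3:30, 1)
    plan <- sample(c("pass", "fail"), n, replace = TRUE, prob = c(.8, .2))
    codegen <- ifelse(plan == "fail", "fail",
                      sample(c("pass", "fail"), n, replace = TRUE))
    execute <- ifelse(codegen == "fail", "fail",
                      sample(c("pass", "fail"), n, replace = TRUE))
    reg <- data.frame(
      case_id = as.character(seq_len(n)), class = "c", task = "t",
      omics = sample(c("genomics", "transcriptomics", "proteomics",
                       "metabolomics"), n, replace = TRUE),
      plan_noacr = plan, codegen_noacr = codegen, execute_noacr = execute,
      plan_acr = plan, codegen_acr = codegen, execute_acr = execute,
      failure_reason = ifelse(plan == "fail" | codegen == "fail" |
                                execute == "fail", "why", ""),
      tools = "x", time_min = 1L, stringsAsFactors = FALSE)
    s <- summarize_evaluation(reg, "no_acr")
    for (stage in c("plan", "codegen", "execute")) {
      cnt <- 0L
      for (i in seq_len(n)) {
        if (reg[[paste0(stage, "_noacr")]][i] == "pass") cnt <- cnt + 1L
      }
      expect_identical(s$counts[[stage]], cnt)
      expect_identical(s$percentages[[stage]], round(100 * cnt / n, 1))
    }
  }
})

test_that("fixture generation is deterministic in (kind, seed)", {
  for (kind in c("rnaseq_deg", "generic_fail_repair")) {
    d1 <- tempfile("det1"); d2 <- tempfile("det2")
    generate_fixture_case(kind, 7, d1)
    generate_fixture_case(kind, 7, d2)
    f1 <- sort(list.files(d1, recursive = TRUE))
    f2 <- sort(list.files(d2, recursive = TRUE))
    expect_identical(f1, f2)
    for (f in f1) {
      expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                       readBin(file.path(d2, f), "raw", 1e6), info = f)
    }
    # a different seed changes the payload
    d3 <- tempfile("det3")
    generate_fixture_case(kind, 8, d3)
    some <- grep("payload/data/(sample_|input)", f1, value = TRUE)[1]
    expect_false(identical(readBin(file.path(d1, some), "raw", 1e6),
                           readBin(file.path(d3, some), "raw", 1e6)))
    unlink(c(d1, d2, d3), recursive = TRUE)
  }
  expect_error(generate_fixture_case("metagenomics_wonder", 1),
               class = "agent_config_error")
})

test_that("synthetic FASTQ payloads are format-valid", {
  with_fixture("rnaseq_deg", 4, function(dir) {
    fastqs <- list.files(file.path(dir, "payload", "data"),
                         pattern = "\\.fastq\\.gz$", full.names = TRUE)
    expect_length(fastqs, 4)
    for (fq in fastqs) {
      lines <- readLines(gzfile(fq))
      expect_identical(length(lines) %% 4L, 0L)
      ids <- lines[seq(1, length(lines), 4)]
      seqs <- lines[seq(2, length(lines), 4)]
      plus <- lines[seq(3, length(lines), 4)]
      quals <- lines[seq(4, length(lines), 4)]
      expect_true(all(startsWith(ids, "@")))
      expect_true(all(plus == "+"))
      expect_identical(nchar(seqs), nchar(quals))
      expect_true(all(grepl("^[ACGT]+$", seqs)))
      expect_gte(length(ids), 40)
    }
  })
})

test_that("the injected-failure fixture always exercises the repair cycle", {
  with_fixture("generic_fail_repair", 9, function(dir) {
    rep <- run_fixture_case(dir)
    expect_true(any(rep$step_outcomes$attempts >= 2))
    expect_true(rep$stage_flags$end_to_end_ok)
  })
})

test_that("the benchmark harness flags exactly the corrupted fixture", {
  base <- tempfile("bench")
  kinds <- c("rnaseq_deg", "chipseq_peaks", "generic_fail_repair")
  dirs <- vapply(kinds, function(k) {
    d <- file.path(base, k)
    generate_fixture_case(k, 2, d)
    d
  }, "")
  br <- run_benchmark(dirs)
  expect_identical(br$n_pass, 3L)
  expect_identical(br$percent_pass, 100)

  # corrupt one transcript: drop the repair entry of generic_fail_repair
  tpath <- file.path(dirs[3], "transcript.json")
  entries <- jsonlite::fromJSON(tpath, simplifyVector = FALSE)
  keep <- Filter(function(e) !grepl("No such file", e$matcher), entries)
  jsonlite::write_json(keep, tpath, auto_unbox = TRUE)
  br2 <- run_benchmark(dirs)
  expect_identical(br2$per_fixture$passed, c(TRUE, TRUE, FALSE))
  # percentages equal a hand computation over the pass/fail vector
  expect_identical(br2$percent_pass,
                   round(100 * sum(br2$per_fixture$passed) /
                           nrow(br2$per_fixture), 1))
  unlink(base, recursive = TRUE)
})
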