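## Synthetic fixture cases: miniature omics workspaces plus scripted
## transcripts that let the full agent loop run hermetically, with no
## real bioinformatics tools and no network.  External tools are stubbed
## by tiny shell scripts staged on PATH inside the workspace: the
## artifact under test is the agent loop, not the aligners.

FIXTURE_KINDS <- c("rnaseq_deg", "chipseq_peaks", "generic_fail_repair")

## deterministic payload writers ----------------------------------------

write_fastq_gz <- function(path, gen, sample, n_reads, read_len = 50L) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_reads)) {
    writeLines(c(
      sprintf("@sim_%s_%d", sample, k),
      lcg_chars(gen, read_len, bases),
      "+",
      strrep("I", read_len)
    ), con)
  }
  invisible(path)
}

write_fasta <- function(path, gen, seqnames, seqlen = 1000L, width = 60L) {
  bases <- c("A", "C", "G", "T")
  lines <- character(0)
  for (nm in seqnames) {
    s <- lcg_chars(gen, seqlen, bases)
    lines <- c(lines, paste0(">", nm),
               substring(s, seq(1, seqlen, width),
                         pmin(seq(1, seqlen, width) + width - 1L, seqlen)))
  }
  writeLines(lines, path)
  invisible(path)
}

write_gtf <- function(path) {
  rows <- c(
    paste0("chr1\tsim\texon\t1\t500\t.\t+\t.\tgene_id \"geneA\";"),
    paste0("chr1\tsim\texon\t501\t1000\t.\t+\t.\tgene_id \"geneB\";"),
    paste0("chr2\tsim\texon\t1\t800\t.\t-\t.\tgene_id \"geneC\";")
  )
  writeLines(rows, path)
  invisible(path)
}

write_stub <- function(dir, name, lines) {
  path <- file.path(dir, name)
  writeLines(c("#!/bin/sh", lines), path)
  Sys.chmod(path, "0755")
  invisible(path)
}

fenced <- function(code_lines) {
  paste(c("```bash", code_lines, "```"), collapse = "\n")
}

# transcript matcher locating a step's sub-goal in the normalized
# CURRENT_GOAL slot (unique there; the same text also appears in history
# summaries, but never preceded by the slot marker)
goal_matcher <- function(goal_text) {
  paste0("<<CURRENT_GOAL>> ", normalize_ws(goal_text))
}

PLANNING_MATCHER <- "Respond with an ordered, numbered step-by-step analysis plan"

## fixture builders ------------------------------------------------------

rnaseq_samples <- c("loglu_1", "loglu_2", "higlu_1", "higlu_2")

build_rnaseq_deg <- function(dir, seed) {
  gen <- lcg_new(seed)
  data_dir <- file.path(dir, "payload", "data")
  bin_dir <- file.path(dir, "payload", "bin")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(bin_dir, recursive = TRUE, showWarnings = FALSE)

  for (s in rnaseq_samples) {
    n <- 48L + lcg_int(gen, 13L)  # 48..60 reads per sample
    write_fastq_gz(file.path(data_dir, sprintf("sample_%s.fastq.gz", s)),
                   gen, s, n)
  }
  write_fasta(file.path(data_dir, "genome.fa"), gen, c("chr1", "chr2"))
  write_gtf(file.path(data_dir, "annotation.gtf"))
  writeLines(c(">TruSeq3_SE_adapter", "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"),
             file.path(data_dir, "TruSeq3-SE.fa"))

  write_stub(bin_dir, "trimmomatic", c(
    '# stub: SE -phred33 IN OUT ILLUMINACLIP:...',
    'in="$3"; out="$4"',
    'cp "$in" "$out"',
    'echo "TrimmomaticSE: Completed successfully" >&2'
  ))
  write_stub(bin_dir, "hisat2-build", c(
    '# stub: hisat2-build REF IDXBASE',
    'cp "$1" "$2.1.ht2"',
    ': > "$2.2.ht2"'
  ))
  write_stub(bin_dir, "hisat2", c(
    'idx=""; reads=""; out=""',
    'while [ $# -gt 0 ]; do case "$1" in',
    '  -x) idx="$2"; shift 2;;',
    '  -U) reads="$2"; shift 2;;',
    '  -S) out="$2"; shift 2;;',
    '  *) shift;;',
    'esac; done',
    'if [ ! -f "${idx}.1.ht2" ]; then',
    '  echo "ERROR: \\"${idx}\\" does not exist or is not a HISAT2 index" >&2',
    '  exit 1',
    'fi',
    'gzip -cd "$reads" | awk \'NR%4==2{printf "r%d\\t0\\tchr1\\t%d\\t60\\t50M\\t%s\\n", NR, NR, $0}\' > "$out"',
    'echo "alignment finished for $reads" >&2'
  ))
  write_stub(bin_dir, "samtools", c(
    'sub="$1"; shift',
    'out=""; in=""',
    'while [ $# -gt 0 ]; do case "$1" in',
    '  -o) out="$2"; shift 2;;',
    '  -*) shift;;',
    '  *) in="$1"; shift;;',
    'esac; done',
    'case "$sub" in',
    '  view) cp "$in" "$out";;',
    '  sort) sort "$in" > "$out";;',
    '  *) echo "samtools stub: unsupported subcommand $sub" >&2; exit 2;;',
    'esac'
  ))
  write_stub(bin_dir, "htseq-count", c(
    '# stub: htseq-count BAM GTF -> gene counts on stdout',
    'bam="$1"; gtf="$2"',
    'n=$(wc -l < "$bam")',
    'grep -o \'gene_id "[^"]*"\' "$gtf" | sed \'s/gene_id "//; s/"$//\' | sort -u | awk -v n="$n" \'{printf "%s\\t%d\\n", $1, n+NR}\''
  ))
  write_stub(bin_dir, "deseq2_analyze", c(
    '# stub: deseq2_analyze lo1 lo2 hi1 hi2 -> CSV of log2 fold changes',
    'awk \'FNR==1{f++} {c[$1"_"f]=$2; g[$1]=1}',
    'END{ print "gene,log2FoldChange";',
    '  for (k in g){ lo=(c[k"_1"]+c[k"_2"])/2; hi=(c[k"_3"]+c[k"_4"])/2;',
    '    if (lo>0) printf "%s,%.4f\\n", k, log(hi/lo)/log(2) } }\' "$1" "$2" "$3" "$4" | sort'
  ))

  fq <- sprintf("./data/sample_%s.fastq.gz", rnaseq_samples)
  steps <- c(
    paste0('Use the "Trimmomatic" software to trim adapters from the ',
           'single-end reads ', paste(fq, collapse = ", "),
           ' using the adapter file ./data/TruSeq3-SE.fa.'),
    paste0('Use the "Hisat2" software to align the trimmed reads to the ',
           'reference genome ./data/genome.fa.'),
    paste0('Use the "Samtools" software to convert the SAM alignment files ',
           'to sorted BAM files.'),
    paste0('Use the "HTSeq" software to count the reads mapped to each gene ',
           'using the annotation file ./data/annotation.gtf.'),
    paste0('Use the "DESeq2" software to identify differentially expressed ',
           'genes from the count files.')
  )
  plan_text <- paste(sprintf("%d. %s", seq_along(steps), steps),
                     collapse = "\n")

  path_head <- c('export PATH="$PWD/bin:$PATH"', 'mkdir -p output')
  loop <- function(body) {
    c(paste0('for s in ', paste(rnaseq_samples, collapse = " "), '; do'),
      paste0("  ", body), 'done')
  }
  code1 <- fenced(c(path_head, loop(paste0(
    'trimmomatic SE -phred33 ./data/sample_${s}.fastq.gz ',
    './output/sample_${s}_trimmed.fastq.gz ',
    'ILLUMINACLIP:./data/TruSeq3-SE.fa:2:30:10'))))
  align_cmd <- paste0(
    'hisat2 -x ./output/genome_index -U ./output/sample_${s}_trimmed.fastq.gz ',
    '-S ./output/sample_${s}.sam')
  code2_broken <- fenced(c(path_head, loop(align_cmd)))
  code2_fixed <- fenced(c(path_head,
                          'hisat2-build ./data/genome.fa ./output/genome_index',
                          loop(align_cmd)))
  code3 <- fenced(c(path_head, loop(paste0(
    'samtools view -bS ./output/sample_${s}.sam -o ./output/sample_${s}.bam && ',
    'samtools sort ./output/sample_${s}.bam -o ./output/sample_${s}.sorted.bam'))))
  code4 <- fenced(c(path_head, loop(paste0(
    'htseq-count ./output/sample_${s}.sorted.bam ./data/annotation.gtf ',
    '> ./output/counts_${s}.txt'))))
  code5 <- fenced(c(path_head, paste0(
    'deseq2_analyze ',
    paste(sprintf("./output/counts_%s.txt", rnaseq_samples), collapse = " "),
    ' > ./output/differential_expression_results.csv')))

  transcript <- list(
    list(matcher_kind = "substring", matcher = PLANNING_MATCHER,
         response = plan_text),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[1]),
         response = code1),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[2]),
         response = code2_broken, max_uses = 1),
    list(matcher_kind = "substring",
         matcher = "does not exist or is not a HISAT2 index",
         response = code2_fixed),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[3]),
         response = code3),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[4]),
         response = code4),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[5]),
         response = code5)
  )

  entries <- c(
    stats::setNames(
      as.list(c("single-end reads in LoGlu group",
                "single-end reads in LoGlu group, replicate 2",
                "single-end reads in HiGlu group",
                "single-end reads in HiGlu group, replicate 2")), fq),
    stats::setNames(list("reference genome"), "./data/genome.fa"),
    stats::setNames(list("genome annotation"), "./data/annotation.gtf")
  )
  list(
    goal = "identify differentially expressed genes between the LoGlu and HiGlu groups",
    data = entries,
    transcript = transcript,
    expected = list(plan_ok = TRUE, n_steps = 5L,
                    statuses = rep("success", 5L),
                    attempts = c(1L, 2L, 1L, 1L, 1L),
                    end_to_end_ok = TRUE)
  )
}

build_chipseq_peaks <- function(dir, seed) {
  gen <- lcg_new(seed)
  data_dir <- file.path(dir, "payload", "data")
  bin_dir <- file.path(dir, "payload", "bin")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(bin_dir, recursive = TRUE, showWarnings = FALSE)

  for (s in c("chip", "input")) {
    n <- 40L + lcg_int(gen, 21L)
    write_fastq_gz(file.path(data_dir, sprintf("%s.fastq.gz", s)), gen, s, n)
  }
  write_fasta(file.path(data_dir, "genome.fa"), gen, "chr1", seqlen = 1200L)

  write_stub(bin_dir, "trim_galore", c(
    'outdir="output"',
    'while [ $# -gt 0 ]; do case "$1" in',
    '  --output_dir) outdir="$2"; shift 2;;',
    '  -*) shift;;',
    '  *) b=$(basename "$1" .fastq.gz); cp "$1" "$outdir/${b}_trimmed.fq.gz"; shift;;',
    'esac; done'
  ))
  write_stub(bin_dir, "bowtie2", c(
    'reads=""; out=""',
    'while [ $# -gt 0 ]; do case "$1" in',
    '  -x) shift 2;;',
    '  -U) reads="$2"; shift 2;;',
    '  -S) out="$2"; shift 2;;',
    '  *) shift;;',
    'esac; done',
    'gzip -cd "$reads" | awk \'NR%4==2{printf "r%d\\t0\\tchr1\\t%d\\t42\\t50M\\t%s\\n", NR, NR, $0}\' > "$out"',
    'echo "overall alignment rate logged on stderr" >&2'
  ))
  write_stub(bin_dir, "macs2", c(
    't=""; n="macs"; outdir="."',
    'shift  # callpeak',
    'while [ $# -gt 0 ]; do case "$1" in',
    '  -t) t="$2"; shift 2;;',
    '  -c) shift 2;;',
    '  -n) n="$2"; shift 2;;',
    '  --outdir) outdir="$2"; shift 2;;',
    '  *) shift;;',
    'esac; done',
    'k=$(wc -l < "$t")',
    'i=1',
    'while [ $i -le 3 ]; do',
    '  printf "chr1\\t%d\\t%d\\t%s_peak_%d\\t%d\\n" $((i*100)) $((i*100+50)) "$n" $i $((k+i))',
    '  i=$((i+1))',
    'done > "$outdir/${n}_peaks.narrowPeak"'
  ))
  write_stub(bin_dir, "bedtools", c(
    '# stub: bedtools sort -i FILE',
    'in="$3"',
    'sort -k1,1 -k2,2n "$in"'
  ))

  steps <- c(
    paste0('Use the "Trim Galore" software to trim adapters from ',
           './data/chip.fastq.gz and ./data/input.fastq.gz.'),
    paste0('Use the "Bowtie2" software to align the trimmed reads to the ',
           'reference genome ./data/genome.fa.'),
    'Use the "MACS2" software to call peaks from the aligned reads.',
    paste0('Use the "BEDTools" software to sort the called peaks into ',
           './output/peaks.sorted.bed.')
  )
  plan_text <- paste(sprintf("%d. %s", seq_along(steps), steps),
                     collapse = "\n")
  path_head <- c('export PATH="$PWD/bin:$PATH"', 'mkdir -p output')
  code1 <- fenced(c(path_head,
                    'trim_galore --output_dir output ./data/chip.fastq.gz',
                    'trim_galore --output_dir output ./data/input.fastq.gz'))
  code2 <- fenced(c(path_head,
                    'bowtie2 -x ./data/genome.fa -U ./output/chip_trimmed.fq.gz -S ./output/chip.sam',
                    'bowtie2 -x ./data/genome.fa -U ./output/input_trimmed.fq.gz -S ./output/input.sam'))
  code3 <- fenced(c(path_head,
                    'macs2 callpeak -t ./output/chip.sam -c ./output/input.sam -n chip --outdir output'))
  code4 <- fenced(c(path_head,
                    'bedtools sort -i ./output/chip_peaks.narrowPeak > ./output/peaks.sorted.bed'))

  transcript <- list(
    list(matcher_kind = "substring", matcher = PLANNING_MATCHER,
         response = plan_text),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[1]),
         response = code1),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[2]),
         response = code2),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[3]),
         response = code3),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[4]),
         response = code4)
  )
  list(
    goal = "identify binding site peaks from the ChIP sample against the input control",
    data = list(
      "./data/chip.fastq.gz" = "single-end ChIP-seq reads, immunoprecipitated sample",
      "./data/input.fastq.gz" = "single-end ChIP-seq reads, input control",
      "./data/genome.fa" = "reference genome"
    ),
    transcript = transcript,
    expected = list(plan_ok = TRUE, n_steps = 4L,
                    statuses = rep("success", 4L),
                    attempts = rep(1L, 4L),
                    end_to_end_ok = TRUE)
  )
}

build_generic_fail_repair <- function(dir, seed) {
  gen <- lcg_new(seed)
  data_dir <- file.path(dir, "payload", "data")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  n <- 20L + lcg_int(gen, 11L)
  writeLines(sprintf("record_%02d\t%d", seq_len(n),
                     vapply(seq_len(n), function(i) lcg_int(gen, 1000L), 1)),
             file.path(data_dir, "input.txt"))

  steps <- c(
    "Validate the input data file ./data/input.txt and report its line count.",
    "Summarize the validated records into ./output/summary.txt."
  )
  plan_text <- paste(sprintf("%d. %s", seq_along(steps), steps),
                     collapse = "\n")
  code1 <- fenced(c('mkdir -p output', 'wc -l ./data/input.txt'))
  code2_broken <- fenced(c('mkdir -p output',
                           'cat ./data/records.txt > ./output/summary.txt'))
  code2_fixed <- fenced(c('mkdir -p output',
                          'sort ./data/input.txt > ./output/summary.txt'))
  transcript <- list(
    list(matcher_kind = "substring", matcher = PLANNING_MATCHER,
         response = plan_text),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[1]),
         response = code1),
    list(matcher_kind = "substring", matcher = goal_matcher(steps[2]),
         response = code2_broken, max_uses = 1),
    list(matcher_kind = "substring", matcher = "No such file or directory",
         response = code2_fixed)
  )
  list(
    goal = "validate and summarize the tabular input data",
    data = list("./data/input.txt" = "tab-separated records, one per line"),
    transcript = transcript,
    expected = list(plan_ok = TRUE, n_steps = 2L,
                    statuses = rep("success", 2L),
                    attempts = c(1L, 2L),
                    end_to_end_ok = TRUE)
  )
}

#' Generate a self-contained fixture case
#'
#' Writes a miniature synthetic workspace under `dir`: sequencing-like
#' payload files (gzipped FASTQ with 4-line records, a small FASTA
#' reference, a GTF annotation, depending on `kind`), stub command-line
#' tools standing in for trimmer/aligner/counter, a scripted backend
#' transcript (for `rnaseq_deg` and `generic_fail_repair` including one
#' injected failure with a use-limited repair entry), a run
#' configuration, and the expected run-report skeleton. Identical
#' `(kind, seed)` pairs produce byte-identical payloads and transcripts;
#' all pseudo-randomness comes from a documented linear congruential
#' generator, independent of R's RNG.
#'
#' @param kind One of `"rnaseq_deg"`, `"chipseq_peaks"`,
#'   `"generic_fail_repair"`.
#' @param seed Non-negative integer seed.
#' @param dir Target directory (created; must not be an existing
#'   non-empty fixture unless `overwrite`).
#' @param overwrite Replace an existing fixture directory?
#' @return `dir`, invisibly classed as `fixture_case` with the expected
#'   skeleton attached.
#' @export
generate_fixture_case <- function(kind, seed, dir = tempfile("fixture_"),
                                  overwrite = FALSE) {
  if (!is_string(kind) || !kind %in% FIXTURE_KINDS) {
    config_error(sprintf("unknown fixture kind: %s (known: %s)",
                         as.character(kind)[1],
                         paste(FIXTURE_KINDS, collapse = ", ")))
  }
  if (!is_count(seed)) validation_error("seed must be a non-negative integer")
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    validation_error(sprintf("fixture directory not empty: %s", dir))
  }
  unlink(dir, recursive = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  spec <- switch(kind,
    rnaseq_deg = build_rnaseq_deg(dir, seed),
    chipseq_peaks = build_chipseq_peaks(dir, seed),
    generic_fail_repair = build_generic_fail_repair(dir, seed)
  )

  jsonlite::write_json(spec$transcript, file.path(dir, "transcript.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_yaml <- yaml::as.yaml(list(
    data = lapply(seq_along(spec$data), function(i) {
      stats::setNames(list(spec$data[[i]]), names(spec$data)[i])
    }),
    goal = spec$goal,
    blacklist = list(),
    backend = "transcript:transcript.json",
    output_dir = "runs",
    limits = list(max_repair_attempts = 5L, temperature = 0,
                  step_timeout = 300)
  ))
  writeLines(cfg_yaml, file.path(dir, "config.yaml"))
  expected <- c(list(kind = kind, seed = seed), spec$expected)
  jsonlite::write_json(expected, file.path(dir, "expected_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(dir, class = "fixture_case", expected = expected))
}

#' Run the agent on one generated fixture
#'
#' Loads the fixture's configuration and transcript, stages the payload
#' (data and stub tools) into a fresh workspace, and runs the full agent
#' loop against the transcript backend.
#'
#' @param dir A fixture directory from [generate_fixture_case()].
#' @param run_id Workspace run id (defaults to a fixed id inside the
#'   fixture, overwritten on re-run so repeated runs are comparable).
#' @param max_repair_attempts Optional override of the fixture's bound.
#' @return The `run_report`.
#' @export
run_fixture_case <- function(dir, run_id = "fixture-run",
                             max_repair_attempts = NULL) {
  cfg <- read_config(file.path(dir, "config.yaml"))
  if (!is.null(max_repair_attempts)) {
    cfg$max_repair_attempts <- as.integer(max_repair_attempts)
  }
  backend <- transcript_backend(file.path(dir, "transcript.json"))
  payload <- file.path(dir, "payload")
  run_agent(cfg, backend = backend, run_id = run_id, overwrite = TRUE,
            workspace_setup = function(ws) {
              for (sub in list.files(payload)) {
                file.copy(file.path(payload, sub), ws$root,
                          recursive = TRUE)
              }
            })
}

report_matches_expected <- function(report, expected) {
  oc <- report$step_outcomes
  isTRUE(report$stage_flags$plan_ok) == isTRUE(expected$plan_ok) &&
    nrow(oc) == expected$n_steps &&
    identical(oc$status, as.character(unlist(expected$statuses))) &&
    identical(oc$attempts, as.integer(unlist(expected$attempts))) &&
    isTRUE(report$stage_flags$end_to_end_ok) == isTRUE(expected$end_to_end_ok)
}

#' Run a benchmark over generated fixtures
#'
#' Runs [run_fixture_case()] on each fixture directory, compares every
#' run report against the fixture's expected skeleton, and summarizes
#' pass rates.
#'
#' @param fixture_dirs Character vector of fixture directories.
#' @param max_repair_attempts Optional override applied to every run.
#' @return A `benchmark_report` with a per-fixture data frame
#'   (`fixture`, `kind`, `passed`, `end_to_end_ok`, `n_steps`) and
#'   overall `n_pass` / `percent_pass`.
#' @export
run_benchmark <- function(fixture_dirs, max_repair_attempts = NULL) {
  stopifnot(length(fixture_dirs) > 0)
  rows <- lapply(fixture_dirs, function(dir) {
    expected <- jsonlite::fromJSON(file.path(dir, "expected_report.json"),
                                   simplifyVector = FALSE)
    report <- run_fixture_case(dir, max_repair_attempts = max_repair_attempts)
    data.frame(
      fixture = dir, kind = expected$kind,
      passed = report_matches_expected(report, expected),
      end_to_end_ok = isTRUE(report$stage_flags$end_to_end_ok),
      n_steps = nrow(report$step_outcomes),
      stringsAsFactors = FALSE
    )
  })
  per_fixture <- do.call(rbind, rows)
  structure(
    list(per_fixture = per_fixture,
         total = nrow(per_fixture),
         n_pass = sum(per_fixture$passed),
         percent_pass = round(100 * mean(per_fixture$passed), 1)),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", x$n_pass, "/", x$total, " fixtures passed (",
      x$percent_pass, "%)\n", sep = "")
  for (i in seq_len(nrow(x$per_fixture))) {
    cat(sprintf("  %-20s %s\n", x$per_fixture$kind[i],
                if (x$per_fixture$passed[i]) "pass" else "FAIL"))
  }
  invisible(x)
}
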