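# Shared helpers: tiny configs, contexts and transcripts built in code.

demo_entries <- function() {
  data.frame(
    path = c("./data/SRR1374921.fastq.gz", "./data/SRR1374922.fastq.gz",
             "./data/SRR1374923.fastq.gz", "./data/SRR1374924.fastq.gz",
             "./data/mm39.fa", "./data/mm39.ncbiRefSeq.gtf"),
    description = c("single-end reads in LoGlu group",
                    "single-end reads in LoGlu group, replicate 2",
                    "single-end reads in HiGlu group",
                    "single-end reads in HiGlu group, replicate 2",
                    "mouse reference genome", "genome annotation"),
    stringsAsFactors = FALSE
  )
}

demo_config_yaml <- function() {
  paste(
    "data:",
    "  - ./data/SRR1374921.fastq.gz: single-end reads in LoGlu group",
    "  - ./data/SRR1374922.fastq.gz: single-end reads in LoGlu group, replicate 2",
    "  - ./data/SRR1374923.fastq.gz: single-end reads in HiGlu group",
    "  - ./data/SRR1374924.fastq.gz: single-end reads in HiGlu group, replicate 2",
    "  - ./data/mm39.fa: mouse reference genome",
    "  - ./data/mm39.ncbiRefSeq.gtf: genome annotation",
    "goal: identify differentially expressed genes",
    sep = "\n"
  )
}

demo_ctx <- function(goal = "identify differentially expressed genes",
                     blacklist = character(0), history = "") {
  prompt_context(blacklist, demo_entries(), goal, history)
}

# the five-step worked plan in ordinal-connective prose style
demo_ordinal_plan <- function() {
  paste0(
    'First, I will use the "Trimmomatic" software to trim the adapters from ',
    'the single-end mouse rna-seq reads. The input files for this step will ',
    'be "./data/SRR1374921.fastq.gz", "./data/SRR1374922.fastq.gz", ',
    '"./data/SRR1374923.fastq.gz", "./data/SRR1374924.fastq.gz" and the ',
    'adapter file "./data/TruSeq3-SE.fa".',
    'Next, I will use the "Hisat2" software to align the trimmed reads to ',
    'the mouse mm39 genome. The input files for this step will be the output ',
    'files from the previous step and the genome file "./data/mm39.fa".',
    'Then, I will use the "Samtools" software to convert the alignment ',
    'output files from Hisat2 (in SAM format) to BAM format.',
    'After that, I will use the "HTSeq" software to count the number of ',
    'reads mapped to each gene. The input files for this step will be the ',
    'BAM files from the previous step and the annotation file ',
    '"./data/mm39.ncbiRefSeq.gtf".',
    'Finally, I will use the "DESeq2" software to identify the ',
    'differentially expressed genes. The input files for this step will be ',
    'the count files from the previous step.'
  )
}

# canonical form of a run report with run-specific fields removed
canonical_report <- function(report) {
  x <- omicsagent:::report_to_list(report)
  x$run_id <- NULL
  x$started <- NULL
  x$ended <- NULL
  x
}

# random printable string (fixed RNG stream of the caller)
rand_string <- function(len = 12, pool = c(letters, LETTERS, 0:9, " ", ".",
                                           "/", "-", "_", "%", "<", ">")) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

with_fixture <- function(kind, seed, code) {
  dir <- file.path(tempfile("fxt"), kind)
  generate_fixture_case(kind, seed, dir)
  on.exit(unlink(dirname(dir), recursive = TRUE), add = TRUE)
  force(code)
  code(dir)
}
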