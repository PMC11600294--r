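Package: omicsagent
Title: Autonomous Planning, Code Generation and Repair for Multi-Omic
    Analysis Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An autonomous agent framework for conventional multi-omic
    bioinformatics analysis.  From three user inputs (data paths, data
    descriptions and a final objective, supplied as YAML) the agent plans
    an ordered analysis, generates shell code for each step through a
    pluggable language-model backend, screens and executes that code in a
    confined workspace, and repairs failing code automatically by feeding
    captured error output back into regeneration.  A deterministic
    transcript-replay backend and synthetic miniature omics fixtures
    (FASTQ/FASTA/GTF plus stubbed command-line tools) make the full agent
    loop testable offline, and a bundled 40-case benchmark registry with a
    stage-wise success-rate summarizer supports evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    curl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
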