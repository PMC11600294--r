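# omicsagent

An R implementation of an autonomous-agent architecture for conventional
multi-omic bioinformatics analysis. From three user inputs — data paths,
data descriptions and a final objective, supplied as YAML — the agent:

1. **plans**: asks a language-model backend for an ordered, numbered
   analysis plan naming the software for each step;
2. **generates code**: asks for a complete shell script per step
   (environment setup, installation, invocation), extracted from one
   fenced code block;
3. **executes**: screens each script against a command denylist, then
   runs it confined to a run workspace with captured stdout/stderr and a
   timeout; and
4. **repairs**: when execution is classified as an error, feeds the
   captured error excerpt back into the code-generation prompt and
   regenerates — the *automatic code repair* (ACR) cycle — until success
   or a retry bound (`min(k, bound) + 1` executions for `k` broken
   attempts before a fix).

The agent keeps a natural-language memory of its actions, re-rendered
into every prompt through four named slots (blacklist, data list,
current goal, history summary). Backends are pluggable behind one
`complete()` contract: an online chat-API adapter, a local
instruct-model adapter, and a deterministic **transcript-replay
backend** that makes the entire loop testable offline — no model, no
network, no real bioinformatics tools. Synthetic miniature omics
workspaces (gzipped FASTQ, FASTA, GTF, plus stubbed command-line tools)
ship as generated fixtures, and a bundled 40-case benchmark registry
records expert-assessed stage outcomes (plan / codegen / execute,
without and with ACR) together with a stage-wise success-rate
summarizer.

The package is for bioinformaticians and tool builders who want to
study, extend or evaluate LLM-agent orchestration for omics pipelines
with a fully reproducible, hermetic harness.

## Worked example

Generate the RNA-seq differential-expression fixture — four synthetic
single-end FASTQ samples in two conditions, a 2 kb reference, a
three-gene annotation, and a scripted transcript that includes one
injected failure (alignment requested before the genome index exists) —
and run the full agent loop on it:

```r
library(omicsagent)

dir <- file.path(tempdir(), "demo")
generate_fixture_case("rnaseq_deg", seed = 7, dir)
report <- run_fixture_case(dir)
print(report)
#> <run_report> run_id=fixture-run
#>   stages: plan_ok=TRUE all_codegen_ok=TRUE end_to_end_ok=TRUE
#>   step 1: success (attempts=1)
#>   step 2: success (attempts=2)
#>   step 3: success (attempts=1)
#>   step 4: success (attempts=1)
#>   step 5: success (attempts=1)
```

The plan was parsed into five software-annotated steps
(trim → align → convert → count → differential expression):

```r
print(report$plan)
#> <analysis_plan> 5 step(s)
#>   1. Use the "Trimmomatic" software to trim adapters from the single-end... [Trimmomatic]
#>   2. Use the "Hisat2" software to align the trimmed reads to the referen... [Hisat2]
#>   3. Use the "Samtools" software to convert the SAM alignment files to s... [Samtools]
#>   4. Use the "HTSeq" software to count the reads mapped to each gene usi... [HTSeq]
#>   5. Use the "DESeq2" software to identify differentially expressed gene... [DESeq2]
```

Step 2 shows `attempts=2`: the first generated script ran the aligner
without building the genome index, the executor captured the index
error, and the repair cycle regenerated a script that builds the index
first. The run ends with the analysis artifact in the workspace:

```r
readLines(file.path(dir, "runs", "fixture-run", "output",
                    "differential_expression_results.csv"))
#> [1] "gene,log2FoldChange" "geneA,0.1478" "geneB,0.1451" "geneC,0.1424"
```

The bundled benchmark registry summarizes to stage-wise success rates:

```r
summarize_evaluation(load_case_registry(), "no_acr")
#> <evaluation_summary> variant=no_acr, 40 cases
#>   plan     36/40 passed (90.0%)
#>   codegen  33/40 passed (82.5%)
#>   execute  26/40 passed (65.0%)
#>   omics: genomics=15, transcriptomics=23, proteomics=1, metabolomics=1
```

With the repair module, codegen and execute each rise to 35/40 (87.5%).

A thin CLI wraps the same functions
(`inst/scripts/omicsagent run --config <file>`, `replay --log <path>`,
`bench generate|run|summarize`); `run` exits 0 iff the run finished end
to end.

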