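---
title: "How omicsagent plans, generates, executes and repairs analysis code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How omicsagent plans, generates, executes and repairs analysis code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsagent)
```

## The model

`omicsagent` implements an autonomous-agent architecture for conventional
multi-omic analysis. The user supplies exactly three things, as YAML: an
ordered list of `path: description` data entries, a free-text final
objective, and (optionally) a blacklist of prohibited software. The agent
then works in three phases:

1. **Planning.** A language-model backend is asked for an ordered,
   numbered analysis plan naming the software for each step.
2. **Code generation.** For each plan step in order, the backend is asked
   for a complete shell script (environment setup, installation,
   invocation), returned as one fenced code block.
3. **Execution.** Each script is screened against a command denylist,
   then run in a confined workspace with captured stdout/stderr and a
   timeout.

When an execution is classified as an error, the *automatic code repair*
(ACR) cycle appends the captured error excerpt to the code-generation
prompt ("previous code / observed error / fix it") and regenerates,
until the script succeeds or a retry bound is exhausted.

The package's central assumption is that the value of this architecture
lies in the orchestration contract — prompt structure, memory format,
repair accounting, sandbox discipline — not in any particular language
model. Every backend sits behind one `complete()` contract, and the test
suite exercises the whole loop through a deterministic transcript-replay
backend.

## Prompts and memory

Every prompt is assembled from four named slots: the **blacklist**, the
**data list** (the `path: description` pairs), the **current goal** (the
global objective during planning; the step's sub-goal during code
generation), and the **history summary**. Templates live as versioned
text files under `inst/templates/`, so wording changes are diffable.

The history summary uses two fixed sentence templates. The planning-phase
memory reads

> First, you provided input in the format 'file path: file description'
> in a list: *data list*. You devised a detailed plan to accomplish your
> overarching objective. Your overarching goal is *global goal*. Your
> plan involves *tasks*.

and each completed step appends

> Then, you successfully completed the task: *task* with the
> corresponding code: *code*.

Only successfully executed steps ever enter the memory — failed attempts
are logged but never summarized, so the history always describes work
that actually happened. The summary is re-rendered into every prompt
(stateless backend calls with full context each time) rather than kept
as a persistent chat session.

Two practical choices here were genuinely open:

* **Token budget.** Context budgets are approximated by a character
  proxy (4 characters per token), avoiding a tokenizer dependency. The
  orchestrator re-renders memory under a 3000-token budget; when the
  text would overflow, the *oldest* completed-task sentences are elided
  and replaced by a count marker. The plan sentence and the most recent
  task sentence are always retained, because the immediately preceding
  step is what the next script most often consumes.
* **Slot escaping.** Slot values are percent-escaped for the template's
  own delimiters, so a data description containing delimiter characters
  cannot break slot boundaries. `extract_prompt_slots()` inverts the
  rendering exactly; the test suite checks this round trip on randomized
  hostile inputs.

## Backends and the transcript replayer

Three backends implement the `complete()` contract: an online chat-API
adapter, a local instruct-model command adapter, and the
`transcript_backend()`. The live adapters are deliberately thin and are
never touched by the test suite; refusals and transport exhaustion are
encoded in the response's `finish_state`, never raised as conditions.

The transcript backend answers prompts from a prerecorded
matcher-to-response table. Prompts are whitespace-normalized, and
declared placeholders substitute run-specific tokens (workspace paths,
run ids) before matching, so transcripts survive temporary directories.
Matchers may be fixed substrings, exact normalized strings, or FNV-1a
32-bit digests of the normalized prompt.

One subtlety deserves a note. Transcript validation rejects two entries
with an identical matcher, yet emulating *regeneration* requires that a
repeated, related prompt get a different answer on the second attempt.
The resolution: entries are tried in file order, entries whose
`max_uses` is exhausted are skipped, and the first live match wins. A
repair scenario therefore records the broken response with
`max_uses = 1` and a fix entry keyed on the error text; the initial
request consumes the broken entry, and the repair prompt — which carries
the error excerpt — lands on the fix.

## The repair loop and its accounting

The repair cycle is bounded by `max_repair_attempts` (default 5, with
`0` disabling repair entirely). An unbounded "retry until success" loop
cannot terminate against a stuck backend, so a bound with a per-run
override is imposed; exhaustion is a reported outcome, not an exception.
The accounting is exact and tested as a property: with `k` broken
responses before a fix, the loop performs `min(k, bound) + 1` executions
and succeeds iff `k <= bound`.

Error excerpts fed back into regeneration are capped at 4000 characters
and tail-biased (stderr before stdout), since shell errors almost always
trail the output. Decoding temperature defaults to 0 for
reproducibility.

## Screening, execution and error classification

Generated scripts are screened line-wise (whole-line comments and
here-document bodies excluded) against a denylist of command patterns:
privilege escalation, machine-state changes, destructive or
permission-changing operations on absolute paths, and piping downloads
straight into a shell. Generated analysis code addresses its inputs with
workspace-relative paths, which is why absolute-path writes are treated
as hostile. A rejection is surfaced to the repair loop as an error
finding (`denylisted_command`), so the agent regenerates instead of
aborting — and a rejected script is *never* executed, which the test
suite verifies from the run log.

Execution prepends `set -e` (fail-fast: a multi-command step reports the
first failing command), runs under the workspace root with a private,
allow-listed environment (`PATH`, `HOME` and `TMPDIR` point into the
workspace), captures both streams to files beside the script
(tail-preserving truncation at 1 MiB per stream), and kills the process
at the policy timeout (default 3600 s per step). An optional container
mode delegates to Docker with only the workspace bind-mounted; it is off
by default so the test suite stays hermetic, and confinement is still
enforced by working-directory discipline plus the denylist.

Classification is **exit-code-primary**: a result is an error iff the
exit code is non-zero, the run timed out, or a configured pattern
(`command not found`, `Traceback`, `Error:`, ...) matches either stream.
Plain non-empty stderr is deliberately *not* an error — aligners,
trimmers and peak callers routinely log progress there, and treating
stderr chatter as failure would send healthy runs into the repair loop.

## Orchestration

`run_agent()` proposes the plan (re-proposing, bounded, when the parsed
plan names blacklisted software — the blacklist is enforced both in the
prompt and post-hoc, because prompt-only prohibition is not verifiable),
then walks the steps in order. The run is **fail-stop**: after the first
step exhausts its repairs, the remaining steps are marked `skipped`
rather than attempted, since downstream bioinformatics steps consume
upstream outputs and continuing would be meaningless. The package does
not re-propose the plan mid-run (no dynamic replanning).

Plan parsing accepts the two styles that planner output actually takes:
explicit numbering and ordinal-connective prose (First / Next / Then /
After that / Finally). Both splitters run; the parse recognizing more
steps wins, with ties going to the numbered parse as the more explicit
one. Software names are recognized from double-quoted tokens plus a
~60-entry lexicon seeded from the benchmark registry's tool column;
unknown quoted tokens are kept as software. Each plan sentence stays one
step — whether multi-tool sentences should split further is undecidable
from planner output alone, and one-step-per-sentence keeps indices
aligned with the numbered source text.

Every prompt, backend response, screening decision, execution and repair
attempt is appended to a JSON-lines run log; `replay_run()` reconstructs
the identical run report from that log without executing anything.

## The synthetic fixture suite

Offline testing needs the full loop — planning, codegen, screening,
execution, repair, memory — without models, tools or network. Fixture
cases therefore stub the external tools with tiny shell scripts staged
on `PATH` inside the workspace: the trimmer copies reads through, the
aligner writes SAM-like lines (and genuinely fails when its index is
missing, which is what the injected-failure scenario exploits), the
counter derives per-gene counts from its input, the differential step
computes log2 fold changes with awk. What passing fixture runs
demonstrate is that the *agent loop* behaves exactly as specified; they
say nothing about the scientific validity of real tools, which is out of
scope by design.

Payloads are deterministic: all pseudo-randomness comes from a linear
congruential generator with documented constants
(`a = 1664525`, `c = 1013904223`, `m = 2^32`), independent of R's RNG,
so identical `(kind, seed)` pairs give byte-identical workspaces. The
problem sizes are deliberately miniature — 48–60 reads of 50 bp per
FASTQ, a 2 kb two-contig reference, a three-gene annotation — chosen so
a full end-to-end run is a desk-scale computation while still exercising
real gzipped FASTQ/FASTA/GTF handling.

Three kinds ship: `rnaseq_deg` (the five-step differential-expression
workflow with one injected alignment failure repaired on the second
attempt), `chipseq_peaks` (a clean four-step peak-calling run), and
`generic_fail_repair` (a minimal broken-then-fixed scenario). They do
not emulate real-data properties — no sequencing error model, no
adapter contamination, no expression signal — because none of those
influence the orchestration behavior under test.

## The benchmark registry

The package bundles a registry of 40 real-world benchmark cases spanning
genomics, transcriptomics, proteomics and metabolomics, with
expert-assessed pass/fail outcomes per stage (plan / codegen / execute)
for runs without and with the repair module, the tools chosen, and
code-generation times. `summarize_evaluation()` reproduces the
stage-wise success rates; validation enforces the stage-implication
chain (an execution success implies codegen success implies plan
success) and that a failure reason is present exactly when a stage
failed.

The with-repair results are aggregate-only at the source: which two of
the three codegen failures were rescued is not recorded per case. The
bundled registry commits to one assignment that reproduces the
aggregates exactly — the wrong-package-name failure (9.1) and the
circular-RNA case (10.8) marked repaired, the case whose tool is simply
absent from conda (10.6) left failed, on the reasoning that regeneration
can fix a name or an invocation but cannot conjure a missing package.
The registry file marks this assignment as inferred.

## Known limitations

* The live chat-API and local-command adapters satisfy the backend
  contract but are exercised offline only through that contract; their
  transport behavior is not covered by the suite.
* Denylist screening is pattern-based over effective script lines; it is
  a guard against obviously destructive generated code, not a security
  boundary. Container mode exists for stronger isolation; network
  policy is not enforced (real runs legitimately install from conda).
* Error classification depends on configurable patterns; a tool that
  fails silently with exit 0 and no recognizable message is classified
  as a success.
* The transcript backend replays what was recorded; it cannot evaluate
  the quality of novel plans, and fixture success rates measure the
  orchestration loop, not model capability.
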