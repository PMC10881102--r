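---
title: "Testing workflow pipelines with wftest: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing workflow pipelines with wftest: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wftest)
```

## The problem

Bioinformatics pipelines built on workflow orchestration engines such as
Nextflow chain many external tools, each with its own release cadence.
A change in any single tool, or in the glue between tools, can silently
alter the final outputs. Manual re-testing after every change does not
scale, so pipeline regressions are routinely caught late or not at all.

`wftest` makes pipeline testing declarative. A developer describes test
cases once, in a YAML file; the harness then assembles the engine command
line for each case, executes it, and validates the outputs. Testing a
pipeline takes three steps: scaffold the framework (`init_scaffold()` or
`wftest init`), fill in the template test definitions, and run them
(`run_command()` or `wftest run`).

## The test model

A suite has two levels of settings:

* **global** — suite-wide defaults: the engine work directory
  (`temp_dir`, passed as `-w`), an engine configuration file applied to
  every case (`nf_config`, passed first as `-c`), the base output
  directory, and the cleanup flags `remove_temp` / `clean_logs`;
* **case-specific** — each named case declares the workflow to run
  (`nf_script`: a local script or an `organization/repository` reference
  the engine fetches itself), configs, profiles, an optional params-file,
  its assertions, and `overrides` for any global field.

On top of both sit per-developer environment variables
(`WFTEST_OUTPUT`, `WFTEST_TEMP`, `WFTEST_LOG_LEVEL`), so output and work
locations can differ between machines without editing the shared test
file.

### Precedence

`resolve_effective_settings()` merges the three levels field by field:

> environment > case override > global > built-in default

Case-over-global is the point of having two levels. Environment-over-file
is a design choice: the environment variables exist precisely so a
developer can redirect paths without touching the shared definitions, and
a variable that lost to a case-level path would not achieve that. The
merge is total — every field resolves to a concrete value — and the test
suite checks it against an independent brute-force lookup oracle on 1000
random set/unset configurations.

`output_dir` is carried through the same hierarchy as every other field,
so the global block and case overrides may set it too; this keeps the
merge uniform and the property test simple. The resolved value is handed
to the pipeline through the engine parameter named by the case's
`output_directory_param_name` (emitted as `--<name> <dir>`), because
output-directory parameter names are pipeline-defined, not engine-defined.
Assertions then resolve their `actual` patterns under that directory —
this is how the harness reconciles settings to locate output files
automatically.

### Selection

`wftest run` with no arguments executes the cases flagged `enabled`
(`enabled` defaults to true, so newly added cases run). Naming cases on
the command line executes exactly those, enabled or not, so cases that
are too slow to run by default stay runnable without editing the test
file. Matching is exact and case-sensitive; duplicates are de-duplicated;
execution always follows file order, never request order, so reports are
deterministic. An unknown name aborts the whole run (exit 2) rather than
silently running a subset.

## Assertions

Three validation methods, per case and in declared order:

1. **completion only** — an empty `asserts` list; the case passes iff
   the engine exits 0. Engine success is the implicit first assertion of
   every case: on a nonzero exit the case fails and no file assertions
   run, since there is nothing trustworthy to compare.
2. **checksum** — the digest of the resolved actual file must equal the
   digest of the stored expected file. Digests are md5 (default) or
   sha512, always of the whole file; column- or region-selective
   comparison belongs in a custom script. md5 is computed with
   `tools::md5sum()`; sha512 is a streamed C implementation compiled
   with the package, checked in the test suite against an independent
   reference utility on seeded random files.
3. **script** — any executable taking two positional arguments, actual
   then expected. Exit 0 is a pass, any nonzero exit a fail; the
   script's output is preserved in the result detail. The exit-status
   convention is the portable lowest common denominator across the
   languages comparator scripts are written in.

Results distinguish **fail** (contents mismatched) from **error**
(infrastructure: missing file, ambiguous glob, non-executable
comparator). The distinction matters in CI: an error means the test
itself is broken, not the pipeline. Assertions are never short-circuited
— a case with one failing assertion still reports all of them.

`resolve_actual()` requires glob patterns to match exactly one file;
zero or multiple matches are errors, because silently picking one of
several candidates would make a green test meaningless.

### The VCF comparator

Variant-calling pipelines emit VCF headers containing run-specific
metadata (dates, command lines, contig orderings), so whole-file
checksums of VCFs fail even when the calls are identical.
`compare_vcf_records()` drops every `#`-prefixed line and compares the
remaining record lines as ordered sequences of strings. Order
sensitivity is deliberate: valid VCFs are coordinate-sorted, so order
differences are real differences, and the contract stays deterministic
and trivially explainable (first differing record index is reported).
No semantic normalization (allele atomization, INFO reordering) is
attempted — a comparator that rewrites records is a different tool with
its own failure modes. Gzip inputs are decompressed transparently,
since compressed bytes embed timestamps and are useless to compare
directly.

### Snapshots

`record_snapshot()` stores digests of a reference run's outputs, keyed
by output-relative path, in `<case>.snapshot.yaml`; `assert_snapshot()`
re-digests the current outputs against it. Two boundary decisions:

* a recorded file that has disappeared is a **fail**, not an error —
  unlike a missing expected file in a checksum assertion, its absence
  is itself a change in pipeline behaviour, which is exactly what a
  snapshot guards against;
* files present in the output directory but absent from the manifest
  are ignored — the manifest records what was asserted, not a full
  directory inventory.

## Execution and cleanup

`build_engine_command()` is a pure function producing the token
sequence: engine binary, `-c` pairs (global config first, so per-case
configs override it — mirroring the settings hierarchy at the engine
level), `run`, the script reference verbatim, a single comma-joined
`-profile`, `-params-file` when set, the output-directory parameter,
and `-w`. Cases run sequentially in selection order; stdout and stderr
are captured to `<case>.stdout.log` / `<case>.stderr.log` next to the
test file.

Cleanup (`remove_temp`, `clean_logs`) applies only to *passing* cases;
a failed case always retains its work directory and logs, because the
first thing a developer needs after a red test is the evidence. Cleanup
never touches expected files or the test definitions, and a deletion
failure is a warning, not a test failure.

Exit codes follow the standard CI contract: 0 all selected cases
passed, 1 at least one case failed, 2 suite-level error (malformed
YAML, validation failure, unknown case names) — in which event no case
is executed.

## What the fixtures emulate

The package tests itself without any workflow engine installed.
`make_stub_engine()` generates a POSIX `sh` script that accepts the full
command surface the harness emits, writes declared output files under
the directory it receives through the `--<param>` argument, optionally
records its argv, and exits with a configured code. An interpreted stub
needs no toolchain and behaves identically on any CI host.

The stub emulates only the engine's *interface*: argument acceptance,
output production, exit status. It does not emulate scheduling,
channels, resume, containers, or remote repository fetching — so a
green harness suite demonstrates that test definitions are parsed,
commands are correctly assembled, outputs are correctly validated, and
verdicts are correctly aggregated, but says nothing about any real
pipeline's behaviour. Synthetic VCFs (`make_vcf()`,
`make_vcf_records()`) are structurally valid, coordinate-sorted single
sample-less records; they exercise the comparator, not a variant
caller. Seeded random files (`make_random_file()`) give reproducible
checksum material; all fixture generators take explicit seeds and
restore the session RNG state.

Problem sizes in the shipped tests: 1000 random configurations for the
settings-merge property, 100 seeded files for checksum agreement, 100
VCF trials (alternating plain/gzip) for comparator invariance, engine
exit codes {0, 1, 2, 130} for status fidelity. These sizes make the
properties convincing while keeping the whole suite in the
tens-of-seconds range.

## Known limitations

* One YAML dialect, one document per file; no includes or inheritance
  between test files.
* No parallel case execution; determinism of logs and reports is
  prioritized over wall-clock time.
* No BAM/CRAM comparators, no semantic VCF normalization, and no
  validation of outputs written to databases or cloud object stores.
* The remote-script heuristic (exactly one `/`, no path prefix, no
  script extension ⇒ `org/repo`) is a convention; a local file
  literally named like `org/repo` must be written `./org/repo`.
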