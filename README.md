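# wftest

Automated testing of Nextflow-style workflow pipelines from R.

Bioinformatics pipelines chain dozens of external tools behind a workflow
orchestration engine; a change to any tool, or to the glue between tools,
can silently change the final outputs. `wftest` makes regression testing
of such pipelines declarative: test cases are defined once in a YAML file,
and the harness assembles the engine command line for each case, executes
it, and validates the outputs.

It is aimed at pipeline developers (variant calling, population genetics,
and any other Nextflow-based workflow) who want test-driven development
without hand-written wrapper scripts.

## The model

A test suite is a YAML file with a two-level settings hierarchy:

* a **global** block — engine work directory, a global engine config
  applied to every case, the base output directory, and cleanup flags;
* **cases** — each names a workflow (local script or `org/repo` reference),
  its configs, profiles and params-file, and its assertions; any global
  field can be overridden per case.

Environment variables (`WFTEST_OUTPUT`, `WFTEST_TEMP`,
`WFTEST_LOG_LEVEL`) sit above both, so per-developer paths never require
editing the shared test file. Resolution is field-by-field with precedence

```
environment  >  case override  >  global  >  built-in default
```

Each case's verdict combines pipeline completion (the engine must exit 0)
with its assertions, evaluated in order and never short-circuited:

* **completion only** — an empty assertion list; pass iff the engine
  exited 0;
* **checksum** — md5 or sha512 whole-file digest of the resolved output
  file must equal that of a stored expected file;
* **script** — any executable taking `actual expected` as its two
  arguments; exit 0 is a pass, anything else a fail;
* **snapshot** — `record_snapshot()` / `assert_snapshot()` validate
  against digests recorded from a reference run instead of curated files.

A header-insensitive VCF comparator, `compare_vcf_records()`, is shipped
for variant-calling outputs whose headers carry run-specific metadata: it
drops all `#`-prefixed lines and compares the record lines as ordered
sequences (plain or gzip input).

## Worked example

Scaffold a suite (`wftest init` from the shell does the same):

```r
library(wftest)
init_scaffold(".")
#> [1] "./test"  "./test/global.config"  "./test/nftest.yaml"
```

`test/nftest.yaml` for a variant-calling case whose VCF headers change
from run to run, validated with the shipped comparator through a small
wrapper script (`test/compare-vcf.R`):

```yaml
global:
  temp_dir: work
  output_dir: output
cases:
- name: strelka-calls
  nf_script: ./main.nf
  profiles: [test, docker]
  output_directory_param_name: output_dir
  asserts:
  - actual: '*.vcf'
    expect: test/expected-calls.vcf
    method: script
    script: test/compare-vcf.R
- name: completion-only
  enabled: no
  nf_script: ./main.nf
  asserts: []
```

```r
run_command("test/nftest.yaml")   # or: wftest run
#> wftest run report: 1 selected, 1 passed, 0 failed
#>   PASS strelka-calls (engine exit 0)
#>     assertion 1: pass — script test/compare-vcf.R exited 0; output:
#>     1 variant records identical (headers ignored)
```

One case was selected because `completion-only` is disabled; running
`run_command("test/nftest.yaml", "completion-only")` (or
`wftest run "completion-only"`) executes it anyway. The return value is
the CI exit code: 0 all passed, 1 any case failed, 2 suite-level error
(malformed YAML, unknown case name — nothing executed).

A thin command-line wrapper is installed under `exec/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "wftest", package = "wftest"))')" \
    run --test-file test/nftest.yaml --engine nextflow
```

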