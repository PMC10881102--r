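Package: wftest
Title: Automated Testing of Nextflow-Style Workflow Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A test harness for workflow pipelines driven by orchestration
    engines such as Nextflow. Test suites are declared in a YAML file with a
    two-level settings hierarchy (global defaults overridden per test case,
    both overridable through environment variables). Each case assembles an
    engine command line from configs, profiles and parameter files, executes
    it, and validates the outputs through completion checks, md5/sha512
    checksum comparison against expected files, custom two-file comparator
    scripts, recorded-snapshot comparison, and a header-insensitive VCF
    record comparator. Includes a scaffolding command that generates a
    template test directory, and fixture generators (stub engine, synthetic
    VCFs, seeded random files) so the harness itself can be tested without a
    workflow engine installed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
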