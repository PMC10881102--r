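# Shared fixtures for the wftest test suite.  Everything is generated in
# code under tempdir(); no stored binary fixtures, no workflow engine.

# Independent reference digest via coreutils (md5sum / sha512sum), with a
# python-hashlib fallback.  This is the oracle the package's own checksum
# path is checked against.
ref_checksum <- function(path, algorithm = c("md5", "sha512")) {
  algorithm <- match.arg(algorithm)
  tool <- paste0(algorithm, "sum")
  if (nzchar(Sys.which(tool))) {
    out <- system2(tool, shQuote(path), stdout = TRUE)
    return(strsplit(out, " ")[[1]][1])
  }
  out <- system2("python", c("-c", shQuote(sprintf(
    "import hashlib,sys; print(hashlib.%s(open(sys.argv[1],'rb').read()).hexdigest())",
    algorithm)), shQuote(path)), stdout = TRUE)
  out[1]
}

# A fresh scratch directory, removed when the calling frame exits.
local_dir <- function(env = parent.frame()) {
  d <- tempfile("wftest-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# Keep the WFTEST_* variables from leaking into tests.
local_clean_env <- function(env = parent.frame()) {
  withr::local_envvar(
    c(WFTEST_OUTPUT = NA, WFTEST_TEMP = NA, WFTEST_LOG_LEVEL = NA),
    .local_envir = env
  )
}

# Write a test-definition YAML from plain lists and return its path.
write_suite_yaml <- function(dir, cases, global = list(),
                             file = "nftest.yaml") {
  path <- file.path(dir, file)
  yaml::write_yaml(list(global = global, cases = cases), path)
  path
}

# A minimal case entry for write_suite_yaml.
yaml_case <- function(name, nf_script = "./main.nf", enabled = TRUE, ...) {
  c(list(name = name, nf_script = nf_script, enabled = enabled), list(...))
}

# A ready-to-run suite directory: stub engine + test file whose cases all
# use the stub.  Returns list(dir, test_file, stub, argv).
local_stub_suite <- function(cases, global = list(), exit_code = 0L,
                             outputs = list(), echo_args = FALSE,
                             env = parent.frame()) {
  dir <- local_dir(env)
  stub <- make_stub_engine(
    stub_behavior(exit_code = exit_code, outputs = outputs,
                  echo_args = echo_args),
    dest = dir
  )
  global <- utils::modifyList(
    list(temp_dir = file.path(dir, "work"),
         output_dir = file.path(dir, "out")),
    global
  )
  test_file <- write_suite_yaml(dir, cases, global)
  list(dir = dir, test_file = test_file, stub = stub,
       argv = paste0(stub, ".argv"))
}

# Tokens recorded by an echo_args stub, one invocation per element.
read_argv_runs <- function(argv_file) {
  tokens <- readLines(argv_file)
  # split on the work-dir flag "-w", which build_engine_command always
  # emits last with its value
  ends <- which(tokens == "-w") + 1L
  if (length(ends) == 0) return(list())
  begins <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(b, e) tokens[b:e], begins, ends)
}

# Quietly run run_command with logging silenced below errors.
quiet_run <- function(...) {
  configure_logging("error")
  withr::defer(configure_logging("info"))
  suppressMessages(run_command(..., quiet = TRUE))
}
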