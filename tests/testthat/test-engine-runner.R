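# Engine command construction, case execution, and cleanup.

eff <- function(temp_dir = "/t", output_dir = "/o", nf_config = NULL,
                remove_temp = FALSE, clean_logs = FALSE) {
  resolve_effective_settings(
    global_settings(temp_dir = temp_dir, output_dir = output_dir,
                    nf_config = nf_config, remove_temp = remove_temp,
                    clean_logs = clean_logs),
    test_case("x", "./main.nf"), env_context()
  )
}

test_that("the command line is assembled in the documented token order", {
  case <- test_case("full", "nf-core/sarek",
                    nf_configs = c("a.config", "b.config"),
                    profiles = c("test", "docker"),
                    params_file = "params.yaml",
                    output_directory_param_name = "outdir")
  tokens <- build_engine_command(eff(nf_config = "global.config"), case)
  expect_identical(tokens, c(
    "nextflow", "-c", "global.config", "-c", "a.config", "-c", "b.config",
    "run", "nf-core/sarek", "-profile", "test,docker",
    "-params-file", "params.yaml", "--outdir", "/o", "-w", "/t"
  ))
})

test_that("optional pieces are omitted and the global config precedes case configs", {
  minimal <- build_engine_command(eff(), test_case("m", "./main.nf"))
  expect_identical(minimal, c("nextflow", "run", "./main.nf",
                              "--output_dir", "/o", "-w", "/t"))
  expect_false("-profile" %in% minimal)
  expect_false("-params-file" %in% minimal)

  with_case_only <- build_engine_command(
    eff(), test_case("c", "./main.nf", nf_configs = "case.config"))
  expect_identical(with_case_only[2:3], c("-c", "case.config"))
})

test_that("command construction is pure and preserves config declaration order", {
  set.seed(21)
  for (trial in seq_len(30)) {
    n_global <- sample(0:1, 1)
    n_case <- sample(0:3, 1)
    global_cfg <- if (n_global) "g.config" else NULL
    case_cfgs <- if (n_case) paste0("c", seq_len(n_case), ".config")
                 else character()
    case <- test_case("t", "./main.nf", nf_configs = case_cfgs)
    settings <- eff(nf_config = global_cfg)
    tokens <- build_engine_command(settings, case)
    expect_identical(tokens, build_engine_command(settings, case))
    seen <- tokens[which(tokens == "-c") + 1L]
    expect_identical(seen, c(global_cfg, case_cfgs))
  }
})

test_that("executing a stub engine records its exit status faithfully", {
  dir <- local_dir()
  settings <- eff(temp_dir = file.path(dir, "w"),
                  output_dir = file.path(dir, "o"))
  case <- test_case("status", "./main.nf")
  for (k in c(0L, 1L, 2L, 130L)) {
    stub <- make_stub_engine(stub_behavior(exit_code = k), dir,
                             name = paste0("stub", k))
    record <- execute_case(settings, case, stub, log_dir = dir)
    expect_s3_class(record, "wf_run_record")
    expect_identical(record$exit_status, k)
    expect_identical(record$command[1], stub)
    expect_true(file.exists(record$stdout_log))
    expect_true(file.exists(record$stderr_log))
  }
})

test_that("a missing engine binary is an infrastructure error before execution", {
  dir <- local_dir()
  settings <- eff(temp_dir = file.path(dir, "w"),
                  output_dir = file.path(dir, "o"))
  expect_error(execute_case(settings, test_case("x", "./main.nf"),
                            file.path(dir, "no-such-engine"),
                            log_dir = dir),
               "engine binary not found")
})

test_that("the stub writes its declared outputs under the output directory", {
  dir <- local_dir()
  stub <- make_stub_engine(
    stub_behavior(outputs = list("calls.vcf" = "rec1\n",
                                 "qc/summary.txt" = "ok")),
    dir
  )
  settings <- eff(temp_dir = file.path(dir, "w"),
                  output_dir = file.path(dir, "o"))
  record <- execute_case(settings, test_case("outs", "./main.nf"), stub,
                         log_dir = dir)
  expect_identical(record$exit_status, 0L)
  expect_identical(readLines(file.path(dir, "o", "calls.vcf")), "rec1")
  expect_identical(readLines(file.path(dir, "o", "qc", "summary.txt"),
                             warn = FALSE),
                   "ok")
})

test_that("engine success with no assertions passes the case", {
  configure_logging("error")
  withr::defer(configure_logging("info"))
  dir <- local_dir()
  stub <- make_stub_engine(stub_behavior(), dir)
  global <- global_settings(temp_dir = file.path(dir, "w"),
                            output_dir = file.path(dir, "o"))
  result <- suppressMessages(
    run_case(global, test_case("done", "./main.nf"), env_context(), stub,
             log_dir = dir))
  expect_true(result$passed)
  expect_identical(result$engine_exit, 0L)
  expect_length(result$assertion_results, 0)
})

test_that("all assertions are evaluated even when one fails", {
  configure_logging("error")
  withr::defer(configure_logging("info"))
  dir <- local_dir()
  stub <- make_stub_engine(
    stub_behavior(outputs = list("good.txt" = "same", "bad.txt" = "diff")),
    dir
  )
  expect_same <- file.path(dir, "expect-same.txt")
  writeBin(charToRaw("same"), expect_same)
  expect_other <- file.path(dir, "expect-other.txt")
  writeBin(charToRaw("other"), expect_other)

  case <- test_case("mixed", "./main.nf", asserts = list(
    assertion_spec("good.txt", expect_same),
    assertion_spec("bad.txt", expect_other)
  ))
  global <- global_settings(temp_dir = file.path(dir, "w"),
                            output_dir = file.path(dir, "o"))
  result <- suppressMessages(
    run_case(global, case, env_context(), stub, log_dir = dir))
  expect_false(result$passed)
  expect_length(result$assertion_results, 2)
  expect_identical(result$assertion_results[[1]]$status, "pass")
  expect_identical(result$assertion_results[[2]]$status, "fail")
})

test_that("an engine failure fails the case without running assertions", {
  configure_logging("error")
  withr::defer(configure_logging("info"))
  dir <- local_dir()
  stub <- make_stub_engine(stub_behavior(exit_code = 1L), dir)
  case <- test_case("broken", "./main.nf", asserts = list(
    assertion_spec("anything.txt", "whatever")
  ))
  global <- global_settings(temp_dir = file.path(dir, "w"),
                            output_dir = file.path(dir, "o"))
  result <- suppressMessages(
    run_case(global, case, env_context(), stub, log_dir = dir))
  expect_false(result$passed)
  expect_identical(result$engine_exit, 1L)
  expect_length(result$assertion_results, 0)
})

test_that("cleanup removes the work directory only for passing cases with the flag set", {
  configure_logging("error")
  withr::defer(configure_logging("info"))
  run_with <- function(dir, exit_code, remove_temp, clean_logs) {
    stub <- make_stub_engine(stub_behavior(exit_code = exit_code), dir)
    global <- global_settings(temp_dir = file.path(dir, "w"),
                              output_dir = file.path(dir, "o"),
                              remove_temp = remove_temp,
                              clean_logs = clean_logs)
    result <- suppressMessages(
      run_case(global, test_case("c", "./main.nf"), env_context(), stub,
               log_dir = dir))
    list(dir = dir, result = result,
         removed = cleanup_case(result))
  }

  passing <- run_with(local_dir(), 0L, remove_temp = TRUE,
                      clean_logs = FALSE)
  expect_identical(passing$removed, file.path(passing$dir, "w"))
  expect_false(dir.exists(file.path(passing$dir, "w")))

  failing <- run_with(local_dir(), 1L, remove_temp = TRUE,
                      clean_logs = TRUE)
  expect_length(failing$removed, 0)
  expect_true(dir.exists(file.path(failing$dir, "w")))
  expect_true(file.exists(failing$result$record$stdout_log))

  lazy <- run_with(local_dir(), 0L, remove_temp = FALSE,
                   clean_logs = FALSE)
  expect_length(lazy$removed, 0)

  logsonly <- run_with(local_dir(), 0L, remove_temp = FALSE,
                       clean_logs = TRUE)
  expect_setequal(logsonly$removed,
                  c(logsonly$result$record$stdout_log,
                    logsonly$result$record$stderr_log))
  # safety: every removed path sits under the work dir or log dir
  roots <- normalizePath(logsonly$dir)
  expect_true(all(startsWith(normalizePath(logsonly$removed,
                                           mustWork = FALSE), roots)))
})
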