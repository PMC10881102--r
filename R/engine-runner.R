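# Assembling the workflow-engine command line, executing one case, and
# post-run cleanup.

#' Build the engine command line for a test case
#'
#' Pure construction of the token sequence handed to the engine: the engine
#' binary; one `-c <path>` pair per configuration file with the global
#' config first so case configs can override it (later engine configs win);
#' `run`; the script path or `org/repo` reference verbatim; a single
#' comma-joined `-profile` argument when profiles are declared;
#' `-params-file` when set; the pipeline's output-directory parameter as
#' `--<name> <output_dir>`; and the work directory as `-w <temp_dir>`.
#'
#' @param settings Effective settings from [resolve_effective_settings()].
#' @param case A [test_case()].
#' @param engine_binary Engine executable token (default `"nextflow"`).
#' @return Character vector of command tokens, engine binary first.
#' @export
build_engine_command <- function(settings, case, engine_binary = "nextflow") {
  stopifnot(inherits(settings, "wf_effective_settings"),
            inherits(case, "wf_test_case"))
  tokens <- engine_binary
  configs <- c(
    if (!is.null(settings$nf_config) && !is.na(settings$nf_config))
      settings$nf_config,
    case$nf_configs
  )
  for (config in configs) tokens <- c(tokens, "-c", config)
  tokens <- c(tokens, "run", case$nf_script)
  if (length(case$profiles) > 0)
    tokens <- c(tokens, "-profile", paste(case$profiles, collapse = ","))
  if (!is.null(case$params_file))
    tokens <- c(tokens, "-params-file", case$params_file)
  tokens <- c(tokens,
              paste0("--", case$output_directory_param_name),
              settings$output_dir,
              "-w", settings$temp_dir)
  tokens
}

#' Execute one test case's engine run
#'
#' Creates the output and work directories if absent, runs the command
#' built by [build_engine_command()] with stdout and stderr captured to
#' per-case log files under `log_dir`, and returns a complete run record
#' whatever the engine's exit status.  A nonzero engine exit is recorded,
#' never raised; only infrastructure problems (missing engine binary,
#' directory creation failure) raise.
#'
#' @inheritParams build_engine_command
#' @param log_dir Directory receiving `<case>.stdout.log` /
#'   `<case>.stderr.log`.
#' @return A list of class `wf_run_record` with fields `case_name`,
#'   `command`, `exit_status`, `stdout_log`, `stderr_log`, `work_dir`,
#'   `started`, `ended`.
#' @export
execute_case <- function(settings, case, engine_binary = "nextflow",
                         log_dir = ".") {
  command <- build_engine_command(settings, case, engine_binary)
  resolved_engine <- Sys.which(engine_binary)
  if (!nzchar(resolved_engine) && !file.exists(engine_binary))
    stop("engine binary not found: ", engine_binary, call. = FALSE)
  for (d in c(settings$output_dir, settings$temp_dir, log_dir)) {
    if (!dir.exists(d) &&
        !dir.create(d, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory: ", d, call. = FALSE)
  }
  safe_name <- gsub("[^A-Za-z0-9._-]", "_", case$name)
  stdout_log <- file.path(log_dir, paste0(safe_name, ".stdout.log"))
  stderr_log <- file.path(log_dir, paste0(safe_name, ".stderr.log"))

  started <- Sys.time()
  exit_status <- suppressWarnings(
    system2(command[1], args = shQuote(command[-1]),
            stdout = stdout_log, stderr = stderr_log)
  )
  ended <- Sys.time()

  structure(
    list(case_name = case$name, command = command,
         exit_status = exit_status, stdout_log = stdout_log,
         stderr_log = stderr_log, work_dir = settings$temp_dir,
         started = started, ended = ended),
    class = "wf_run_record"
  )
}

#' Run one test case end to end
#'
#' Resolves the case's effective settings, executes the engine, and — only
#' if the engine exited 0 — evaluates every declared assertion in order.
#' Successful completion is the implicit first assertion: an engine
#' failure fails the case with no assertion results.  Assertions are never
#' short-circuited, so a failing case still reports every comparison.
#'
#' @param global A [global_settings()] object.
#' @param case A [test_case()].
#' @param env An [env_context()].
#' @inheritParams execute_case
#' @return A list of class `wf_case_result` with fields `case_name`,
#'   `engine_exit`, `assertion_results`, `passed`, plus the underlying
#'   `record` and resolved `settings`.
#' @export
run_case <- function(global, case, env = env_context(),
                     engine_binary = "nextflow", log_dir = ".") {
  settings <- resolve_effective_settings(global, case, env)
  wf_log("info", "case '%s': starting (%s)", case$name, case$nf_script)
  record <- execute_case(settings, case, engine_binary, log_dir)
  wf_log("info", "case '%s': engine exited %d", case$name,
         record$exit_status)

  if (record$exit_status != 0L) {
    results <- list()
    passed <- FALSE
  } else {
    results <- vector("list", length(case$asserts))
    for (i in seq_along(case$asserts)) {
      results[[i]] <- run_assertion(case$asserts[[i]],
                                    settings$output_dir, index = i)
      wf_log("info", "case '%s': assertion %d %s — %s", case$name, i,
             results[[i]]$status, results[[i]]$detail)
    }
    statuses <- vapply(results, function(r) r$status, character(1))
    passed <- all(statuses == "pass")
  }
  wf_log("info", "case '%s': %s", case$name,
         if (passed) "PASS" else "FAIL")

  structure(
    list(case_name = case$name, engine_exit = record$exit_status,
         assertion_results = results, passed = passed,
         record = record, settings = settings),
    class = "wf_case_result"
  )
}

#' Post-run cleanup for a finished case
#'
#' Honors the cleanup flags only for passing cases: `remove_temp` deletes
#' the engine work directory, `clean_logs` the captured engine log files.
#' A failed case retains everything for debugging regardless of the
#' flags.  Expected files and the test-definition file are never touched.
#'
#' @param result A `wf_case_result` from [run_case()].
#' @param record The case's `wf_run_record` (defaults to the one embedded
#'   in `result`).
#' @param settings The case's effective settings (defaults likewise).
#' @return Character vector of removed paths (possibly empty), invisibly.
#' @export
cleanup_case <- function(result, record = result$record,
                         settings = result$settings) {
  stopifnot(inherits(result, "wf_case_result"))
  removed <- character()
  if (!isTRUE(result$passed)) return(invisible(removed))
  if (isTRUE(settings$remove_temp) && dir.exists(record$work_dir)) {
    status <- unlink(record$work_dir, recursive = TRUE)
    if (status == 0) removed <- c(removed, record$work_dir)
    else warning("could not remove work directory: ", record$work_dir,
                 call. = FALSE)
  }
  if (isTRUE(settings$clean_logs)) {
    for (log in c(record$stdout_log, record$stderr_log)) {
      if (file.exists(log)) {
        if (unlink(log) == 0) removed <- c(removed, log)
        else warning("could not remove log file: ", log, call. = FALSE)
      }
    }
  }
  invisible(removed)
}
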