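# Test-definition data model: global settings, test cases, assertion specs,
# the environment context, and resolution of effective per-case settings.

# Built-in defaults applied when neither environment, case nor global block
# sets a field.  Paths are relative to the working directory the suite is
# launched from.
.wf_defaults <- list(
  temp_dir    = "wftest-temp",
  output_dir  = "wftest-output",
  nf_config   = NA_character_,
  remove_temp = FALSE,
  clean_logs  = FALSE
)

.wf_algorithms <- c("md5", "sha512")
.wf_methods    <- c("checksum", "script")
.wf_log_levels <- c("debug", "info", "warning", "error")

#' Suite-wide default settings
#'
#' Holds the global level of the two-level settings hierarchy: the engine
#' work (temporary) directory, an optional engine configuration file applied
#' to every case, and post-run cleanup flags.  Any field left `NULL` falls
#' back to a built-in default during [resolve_effective_settings()].
#'
#' @param temp_dir Engine work-directory root, or `NULL` for the default.
#' @param nf_config Path to a global engine configuration file, or `NULL`.
#'   Existence is checked at run time, not at parse time.
#' @param remove_temp Delete the engine work directory after a passing case?
#' @param clean_logs Delete captured engine log files after a passing case?
#' @param output_dir Base output directory for case results, or `NULL`.
#' @return An object of class `wf_global_settings`.
#' @seealso [test_case()], [resolve_effective_settings()]
#' @export
global_settings <- function(temp_dir = NULL, nf_config = NULL,
                            remove_temp = NULL, clean_logs = NULL,
                            output_dir = NULL) {
  structure(
    list(temp_dir = temp_dir, nf_config = nf_config,
         remove_temp = remove_temp, clean_logs = clean_logs,
         output_dir = output_dir),
    class = "wf_global_settings"
  )
}

#' One output-validation rule for a test case
#'
#' @param actual Glob pattern resolved relative to the case's effective
#'   output directory; must match exactly one file at assertion time.
#' @param expect Path to the expected artifact.
#' @param method `"checksum"` (digest equality with `expect`) or `"script"`
#'   (run an external two-argument comparator).
#' @param algorithm Digest algorithm for checksum assertions: `"md5"`
#'   (default) or `"sha512"`.
#' @param script Path to an executable comparator; required iff
#'   `method = "script"`.
#' @return An object of class `wf_assertion_spec`.
#' @export
assertion_spec <- function(actual, expect, method = "checksum",
                           algorithm = "md5", script = NULL) {
  structure(
    list(actual = actual, expect = expect, method = method,
         algorithm = algorithm, script = script),
    class = "wf_assertion_spec"
  )
}

#' One named test case
#'
#' A test case names the workflow to run (a local script path or an
#' `organization/repository` reference fetched by the engine itself), the
#' engine configuration to run it with, and the assertions validating its
#' outputs.  `overrides` may re-set any [global_settings()] field for this
#' case only.
#'
#' @param name Unique, non-empty case name; the key used for selection on
#'   the command line.
#' @param nf_script Workflow reference: local path or `org/repo`.
#' @param message Free-text description.
#' @param enabled Run this case by default? Defaults to `TRUE`.
#' @param nf_configs Ordered character vector of config file paths.
#' @param profiles Ordered character vector of configuration profile names.
#' @param params_file Optional parameter-file path.
#' @param output_directory_param_name Name of the engine parameter through
#'   which the pipeline receives its output directory (pipeline-defined;
#'   default `"output_dir"`).
#' @param asserts List of [assertion_spec()] objects (may be empty, meaning
#'   the case only tests successful completion).
#' @param overrides Named list of per-case values for global fields.
#' @return An object of class `wf_test_case`.
#' @export
test_case <- function(name, nf_script, message = "", enabled = TRUE,
                      nf_configs = character(), profiles = character(),
                      params_file = NULL,
                      output_directory_param_name = "output_dir",
                      asserts = list(), overrides = list()) {
  structure(
    list(name = name, message = message, enabled = enabled,
         nf_script = nf_script, nf_configs = as.character(nf_configs),
         profiles = as.character(profiles), params_file = params_file,
         output_directory_param_name = output_directory_param_name,
         asserts = asserts, overrides = overrides),
    class = "wf_test_case"
  )
}

#' Per-developer environment overrides
#'
#' Settings supplied through environment variables so developers can point
#' output and work directories at their own locations without editing the
#' shared test-definition file.  Environment values take precedence over
#' both case-level and global file settings.
#'
#' @param output_dir,temp_dir,log_level Optional overrides; `NULL` leaves
#'   the file-based settings untouched.
#' @return An object of class `wf_env_context`.
#' @export
env_context <- function(output_dir = NULL, temp_dir = NULL,
                        log_level = NULL) {
  if (!is.null(log_level) && !log_level %in% .wf_log_levels)
    stop("unknown log level: ", log_level, call. = FALSE)
  structure(
    list(output_dir = output_dir, temp_dir = temp_dir,
         log_level = log_level),
    class = "wf_env_context"
  )
}

#' Read the environment context from process environment variables
#'
#' Reads `WFTEST_OUTPUT`, `WFTEST_TEMP` and `WFTEST_LOG_LEVEL`; unset or
#' empty variables leave the corresponding field unset.
#'
#' @return An [env_context()] object.
#' @export
env_context_from_env <- function() {
  val <- function(var) {
    v <- Sys.getenv(var, unset = "")
    if (nzchar(v)) v else NULL
  }
  env_context(output_dir = val("WFTEST_OUTPUT"),
              temp_dir = val("WFTEST_TEMP"),
              log_level = val("WFTEST_LOG_LEVEL"))
}

#' Resolve the settings one case will actually run with
#'
#' Merges the three levels of the settings hierarchy field by field with
#' precedence environment > case override > global > built-in default, and
#' returns fully concrete effective settings.  The returned `output_dir` is
#' the directory assertions resolve their `actual` patterns against; the
#' engine receives it through the parameter named by the case's
#' `output_directory_param_name`.
#'
#' @param global A [global_settings()] object.
#' @param case A [test_case()] object.
#' @param env An [env_context()] object.
#' @return A list of class `wf_effective_settings` with fields `temp_dir`,
#'   `output_dir`, `nf_config`, `remove_temp` and `clean_logs`, all
#'   concrete (`nf_config` is `NA` when no level sets it).
#' @export
resolve_effective_settings <- function(global, case, env = env_context()) {
  stopifnot(inherits(global, "wf_global_settings"),
            inherits(case, "wf_test_case"),
            inherits(env, "wf_env_context"))
  pick <- function(field) {
    for (value in list(env[[field]], case$overrides[[field]],
                       global[[field]])) {
      if (!is.null(value)) return(value)
    }
    .wf_defaults[[field]]
  }
  structure(
    list(temp_dir    = pick("temp_dir"),
         output_dir  = pick("output_dir"),
         nf_config   = pick("nf_config"),
         remove_temp = pick("remove_temp"),
         clean_logs  = pick("clean_logs")),
    class = "wf_effective_settings"
  )
}

#' Select the cases a run will execute
#'
#' With no requested names, returns the cases flagged `enabled`, in file
#' order.  With names, returns exactly the named cases — still in file
#' order, duplicates de-duplicated — regardless of their `enabled` flag, so
#' cases disabled by default can be run without editing the test file.
#' Matching is exact and case-sensitive.
#'
#' @param cases List of [test_case()] objects in file order.
#' @param requested_names Character vector of case names; may be empty.
#' @return The selected subset of `cases`, in file order.
#' @export
select_cases <- function(cases, requested_names = character()) {
  all_names <- vapply(cases, function(x) x$name, character(1))
  if (length(requested_names) == 0) {
    enabled <- vapply(cases, function(x) isTRUE(x$enabled), logical(1))
    return(cases[enabled])
  }
  requested_names <- unique(requested_names)
  unknown <- setdiff(requested_names, all_names)
  if (length(unknown) > 0)
    stop("unknown test case name(s): ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  cases[all_names %in% requested_names]
}

#' Validate a parsed suite against the schema invariants
#'
#' Checks every type invariant of the test-definition model and returns the
#' violations as data rather than raising: each finding names the case, the
#' field and the rule violated.  An empty result means the suite is valid.
#'
#' @param global A [global_settings()] object.
#' @param cases List of [test_case()] objects.
#' @return A data frame with columns `case`, `field`, `rule`.
#' @export
validate_suite <- function(global, cases) {
  findings <- list()
  flag <- function(case, field, rule) {
    findings[[length(findings) + 1L]] <<-
      data.frame(case = case, field = field, rule = rule,
                 stringsAsFactors = FALSE)
  }

  names_seen <- vapply(cases, function(x)
    if (is.null(x$name)) "" else as.character(x$name), character(1))
  for (dup in unique(names_seen[duplicated(names_seen) & nzchar(names_seen)]))
    flag(dup, "name", "case names must be unique within a test file")

  for (case in cases) {
    cname <- if (is.null(case$name) || !nzchar(case$name)) "<unnamed>"
             else case$name
    if (is.null(case$name) || !is.character(case$name) || !nzchar(case$name))
      flag(cname, "name", "name must be a non-empty string")
    if (is.null(case$nf_script) || !nzchar(case$nf_script))
      flag(cname, "nf_script", "nf_script must be non-empty")
    if (!is.logical(case$enabled) || length(case$enabled) != 1L ||
        is.na(case$enabled))
      flag(cname, "enabled", "enabled must be a single logical")

    for (field in names(case$overrides)) {
      if (!field %in% names(.wf_defaults)) {
        flag(cname, field, "unknown override field")
        next
      }
      want_logical <- is.logical(.wf_defaults[[field]])
      have_logical <- is.logical(case$overrides[[field]])
      if (want_logical != have_logical)
        flag(cname, field,
             "override type must match the global field type")
    }

    for (i in seq_along(case$asserts)) {
      a <- case$asserts[[i]]
      where <- paste0("asserts[", i, "]")
      if (is.null(a$actual) || !nzchar(a$actual))
        flag(cname, where, "assertion 'actual' pattern is required")
      if (is.null(a$expect) || !nzchar(a$expect))
        flag(cname, where, "assertion 'expect' path is required")
      if (is.null(a$method) || !a$method %in% .wf_methods) {
        flag(cname, where, paste0("unsupported assertion method: ",
                                  a$method %||% "<missing>"))
        next
      }
      if (a$method == "script" && is.null(a$script))
        flag(cname, where, "method 'script' requires a script path")
      if (a$method == "checksum" && !is.null(a$script))
        flag(cname, where, "method 'checksum' must not set a script")
      if (a$method == "checksum" && !a$algorithm %in% .wf_algorithms)
        flag(cname, where,
             paste0("unsupported checksum algorithm: ", a$algorithm))
    }
  }

  if (length(findings) == 0)
    return(data.frame(case = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.wf_known_top_keys    <- c("global", "cases")
.wf_known_global_keys <- names(.wf_defaults)
.wf_known_case_keys   <- c("name", "message", "enabled", "nf_script",
                           "nf_configs", "profiles", "params_file",
                           "output_directory_param_name", "asserts",
                           "overrides")
.wf_known_assert_keys <- c("actual", "expect", "method", "algorithm",
                           "script")

#' Load and validate a YAML test-definition file
#'
#' Parses the suite, builds the typed model, and runs [validate_suite()];
#' any schema violation raises an error naming the case and field.
#' Unrecognized keys are reported as warnings, not errors, so test files
#' remain forward compatible.
#'
#' The expected document layout is a `global` mapping plus a `cases` list;
#' see [init_scaffold()] for a commented template.
#'
#' @param path Path to the YAML test-definition file.
#' @return A list of class `wf_suite` with elements `global`
#'   ([global_settings()]) and `cases` (list of [test_case()] in file
#'   order).
#' @export
load_test_file <- function(path) {
  if (!file.exists(path))
    stop("test file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e)
      stop("malformed YAML in ", path, ": ", conditionMessage(e),
           call. = FALSE)
  )
  if (is.null(doc)) doc <- list()
  if (!is.list(doc))
    stop("malformed YAML in ", path,
         ": top level must be a mapping", call. = FALSE)

  unknown <- setdiff(names(doc), .wf_known_top_keys)
  if (length(unknown) > 0)
    warning("ignoring unrecognized top-level key(s) in ", path, ": ",
            paste(unknown, collapse = ", "), call. = FALSE)

  g <- doc$global %||% list()
  unknown_g <- setdiff(names(g), .wf_known_global_keys)
  if (length(unknown_g) > 0)
    warning("ignoring unrecognized global key(s): ",
            paste(unknown_g, collapse = ", "), call. = FALSE)
  global <- global_settings(
    temp_dir = g$temp_dir, nf_config = g$nf_config,
    remove_temp = g$remove_temp, clean_logs = g$clean_logs,
    output_dir = g$output_dir
  )

  cases <- lapply(doc$cases %||% list(), .wf_case_from_yaml)

  for (required in c("name", "nf_script")) {
    for (i in seq_along(cases)) {
      if (is.null(cases[[i]][[required]]) ||
          !nzchar(cases[[i]][[required]] %||% ""))
        stop("case ", i, " (",
             cases[[i]]$name %||% "<unnamed>",
             "): required field '", required, "' is missing",
             call. = FALSE)
    }
  }

  findings <- validate_suite(global, cases)
  if (nrow(findings) > 0) {
    msgs <- sprintf("case '%s', field '%s': %s",
                    findings$case, findings$field, findings$rule)
    stop("invalid test file ", path, ":\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }

  structure(list(global = global, cases = cases), class = "wf_suite")
}

.wf_case_from_yaml <- function(y) {
  if (!is.list(y))
    stop("each entry under 'cases' must be a mapping", call. = FALSE)
  unknown <- setdiff(names(y), .wf_known_case_keys)
  if (length(unknown) > 0)
    warning("ignoring unrecognized case key(s) in '",
            y$name %||% "<unnamed>", "': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  asserts <- lapply(y$asserts %||% list(), function(a) {
    unknown_a <- setdiff(names(a), .wf_known_assert_keys)
    if (length(unknown_a) > 0)
      warning("ignoring unrecognized assertion key(s): ",
              paste(unknown_a, collapse = ", "), call. = FALSE)
    assertion_spec(actual = a$actual %||% "",
                   expect = a$expect %||% "",
                   method = a$method %||% "checksum",
                   algorithm = a$algorithm %||% "md5",
                   script = a$script)
  })
  test_case(
    name = y$name %||% "", nf_script = y$nf_script %||% "",
    message = y$message %||% "",
    enabled = y$enabled %||% TRUE,
    nf_configs = unlist(y$nf_configs) %||% character(),
    profiles = unlist(y$profiles) %||% character(),
    params_file = y$params_file,
    output_directory_param_name =
      y$output_directory_param_name %||% "output_dir",
    asserts = asserts,
    overrides = y$overrides %||% list()
  )
}

#' Serialize a suite back to YAML
#'
#' Inverse of [load_test_file()] up to field defaults: a parsed suite
#' written out and re-parsed is structurally equal to the original.
#'
#' @param suite A `wf_suite` object.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_test_file <- function(suite, path) {
  stopifnot(inherits(suite, "wf_suite"))
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  doc <- list(
    global = drop_null(unclass(suite$global)),
    cases = lapply(suite$cases, function(case) {
      y <- drop_null(unclass(case))
      y$asserts <- lapply(case$asserts,
                          function(a) drop_null(unclass(a)))
      if (length(y$overrides) == 0) y$overrides <- NULL
      y
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Whether a workflow reference is a remote org/repo
#'
#' A value with exactly one `/`, no leading `./` or `/`, and no recognized
#' script extension is treated as an `organization/repository` reference to
#' be fetched by the engine; anything else is a local script path.
#'
#' @param nf_script Workflow reference string.
#' @return `TRUE` for a remote repository reference.
#' @export
is_remote_script <- function(nf_script) {
  if (grepl("^(\\./|/)", nf_script)) return(FALSE)
  if (lengths(regmatches(nf_script, gregexpr("/", nf_script))) != 1L)
    return(FALSE)
  !grepl("\\.(nf|config|groovy)$", nf_script)
}
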