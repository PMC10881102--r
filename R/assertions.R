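# Output-validation methods: checksum and script assertions, actual-file
# resolution, the header-insensitive VCF record comparator, and snapshot
# record/compare.
#
# Status taxonomy: "fail" means content mismatched; "error" is reserved for
# infrastructure problems (missing files, unresolvable patterns,
# non-executable comparators).  The one deliberate exception is snapshot
# comparison, where a recorded output that has disappeared is itself a
# content change and therefore a fail.

#' Construct an assertion result
#'
#' @param status One of `"pass"`, `"fail"`, `"error"`.
#' @param detail Human-readable explanation (digests compared, script exit
#'   code, resolution failure, ...).
#' @param index Ordinal of the assertion within its test case, if any.
#' @return An object of class `wf_assertion_result`.
#' @export
assertion_result <- function(status, detail = "", index = NA_integer_) {
  stopifnot(status %in% c("pass", "fail", "error"))
  structure(list(index = index, status = status, detail = detail),
            class = "wf_assertion_result")
}

#' @export
print.wf_assertion_result <- function(x, ...) {
  cat(sprintf("[%s] %s\n", toupper(x$status), x$detail))
  invisible(x)
}

#' Digest a file
#'
#' Computes the md5 or sha512 digest of a file's bytes, streamed in chunks
#' so memory use does not grow with file size.
#'
#' @param path Path to a readable regular file.
#' @param algorithm `"md5"` or `"sha512"`.
#' @return Lowercase hexadecimal digest string (32 characters for md5, 128
#'   for sha512).
#' @export
compute_checksum <- function(path, algorithm = c("md5", "sha512")) {
  algorithm <- match.arg(algorithm)
  if (!file.exists(path) || dir.exists(path))
    stop("cannot checksum '", path, "': not a readable file",
         call. = FALSE)
  if (algorithm == "md5") {
    digest <- unname(tools::md5sum(path))
    if (is.na(digest))
      stop("cannot checksum '", path, "': read failed", call. = FALSE)
    tolower(digest)
  } else {
    .Call("wf_sha512_file", path.expand(path), PACKAGE = "wftest")
  }
}

#' Resolve an assertion's actual file under the output directory
#'
#' Expands the glob pattern relative to `output_dir` and insists on a
#' unique match; ambiguity is never silently resolved.
#'
#' @param pattern Glob pattern (or literal relative path).
#' @param output_dir Directory the case wrote its outputs to.
#' @return The single matching file path.
#' @export
resolve_actual <- function(pattern, output_dir) {
  if (!dir.exists(output_dir))
    stop("output directory does not exist: ", output_dir, call. = FALSE)
  hits <- Sys.glob(file.path(output_dir, pattern))
  hits <- hits[!dir.exists(hits)]
  if (length(hits) == 0)
    stop("no actual file matching '", pattern, "' under ", output_dir,
         call. = FALSE)
  if (length(hits) > 1)
    stop("pattern '", pattern, "' is ambiguous under ", output_dir, ": ",
         paste(hits, collapse = ", "), call. = FALSE)
  hits
}

#' Checksum assertion
#'
#' Passes iff the digests of the actual and expected files agree under the
#' given algorithm; the detail message carries both digests.
#'
#' @param actual,expect File paths to compare.
#' @param algorithm Digest algorithm, as in [compute_checksum()].
#' @return An [assertion_result()]; a missing file yields status `"error"`,
#'   never `"fail"`.
#' @export
assert_checksum <- function(actual, expect, algorithm = "md5") {
  digests <- tryCatch(
    list(actual = compute_checksum(actual, algorithm),
         expect = compute_checksum(expect, algorithm)),
    error = function(e) e
  )
  if (inherits(digests, "error"))
    return(assertion_result("error", conditionMessage(digests)))
  status <- if (identical(digests$actual, digests$expect)) "pass" else "fail"
  assertion_result(status, sprintf(
    "%s(%s) = %s vs %s(%s) = %s", algorithm, actual, digests$actual,
    algorithm, expect, digests$expect))
}

#' Custom-script assertion
#'
#' Runs an external comparator with exactly two positional arguments, the
#' actual file then the expected file.  Exit status 0 is a pass; any
#' nonzero exit is a fail with the script's output preserved in the
#' detail.
#'
#' @param script Path to an executable comparator.
#' @param actual,expect File paths handed to the comparator.
#' @return An [assertion_result()]; a missing or non-executable script
#'   yields status `"error"`.
#' @export
assert_script <- function(script, actual, expect) {
  if (!file.exists(script))
    return(assertion_result("error",
                            paste0("comparator script not found: ", script)))
  if (file.access(script, mode = 1) != 0)
    return(assertion_result("error",
                            paste0("comparator script not executable: ",
                                   script)))
  out <- suppressWarnings(
    system2(normalizePath(script), args = shQuote(c(actual, expect)),
            stdout = TRUE, stderr = TRUE)
  )
  code <- attr(out, "status") %||% 0L
  status <- if (code == 0L) "pass" else "fail"
  assertion_result(status, sprintf(
    "script %s exited %d%s", script, code,
    if (length(out) > 0) paste0("; output: ", paste(out, collapse = " | "))
    else ""))
}

#' Compare two VCFs by their variant records, ignoring headers
#'
#' Drops every `#`-prefixed line (meta-information lines and the `#CHROM`
#' column header) from both files and compares the remaining record lines
#' as ordered sequences of strings, insensitive to a trailing newline.
#' Valid VCFs are coordinate-sorted, so order-sensitive comparison is both
#' deterministic and sufficient.  Gzip-compressed inputs are decompressed
#' transparently.
#'
#' @param file_a,file_b VCF file paths (plain text or gzip).
#' @return An [assertion_result()]; on fail, the detail reports the first
#'   differing record index.
#' @export
compare_vcf_records <- function(file_a, file_b) {
  read_records <- function(path) {
    if (!file.exists(path))
      stop("cannot read VCF: ", path, call. = FALSE)
    con <- gzfile(path, "rt")   # reads plain text unchanged
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    lines[!startsWith(lines, "#")]
  }
  recs <- tryCatch(list(a = read_records(file_a), b = read_records(file_b)),
                   error = function(e) e)
  if (inherits(recs, "error"))
    return(assertion_result("error", conditionMessage(recs)))

  n <- min(length(recs$a), length(recs$b))
  differs <- if (n > 0) which(recs$a[seq_len(n)] != recs$b[seq_len(n)])
             else integer()
  first_diff <- if (length(differs) > 0) differs[1]
                else if (length(recs$a) != length(recs$b)) n + 1L
                else NA_integer_
  if (is.na(first_diff))
    return(assertion_result("pass", sprintf(
      "%d variant records identical (headers ignored)", length(recs$a))))
  assertion_result("fail", sprintf(
    "variant records differ at record %d (%d vs %d records)",
    first_diff, length(recs$a), length(recs$b)))
}

#' Record a snapshot of a case's outputs
#'
#' Resolves each assertion's actual file under `output_dir` and stores its
#' digest, keyed by output-relative path, in a manifest written as
#' `<case_name>.snapshot.yaml` under `manifest_dir`.  Later runs can be
#' validated against the manifest with [assert_snapshot()] instead of
#' hand-curated expected files.
#'
#' @param case_name Name of the test case the snapshot belongs to.
#' @param output_dir Directory holding the outputs of a successful run.
#' @param asserts List of [assertion_spec()] whose `actual` patterns name
#'   the files to record.
#' @param algorithm Digest algorithm recorded for every entry.
#' @param manifest_dir Directory the manifest file is written to.
#' @return The manifest, an object of class `wf_snapshot_manifest`.
#' @export
record_snapshot <- function(case_name, output_dir, asserts,
                            algorithm = "md5", manifest_dir = "test") {
  entries <- list()
  for (spec in asserts) {
    actual <- resolve_actual(spec$actual, output_dir)
    rel <- .wf_relpath(actual, output_dir)
    entries[[rel]] <- list(algorithm = algorithm,
                           digest = compute_checksum(actual, algorithm))
  }
  manifest <- structure(
    list(case_name = case_name,
         created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         entries = entries),
    class = "wf_snapshot_manifest"
  )
  if (!dir.exists(manifest_dir))
    dir.create(manifest_dir, recursive = TRUE)
  path <- file.path(manifest_dir, paste0(case_name, ".snapshot.yaml"))
  yaml::write_yaml(unclass(manifest), path)
  attr(manifest, "path") <- path
  manifest
}

#' Read a snapshot manifest from disk
#'
#' @param path Path to a `*.snapshot.yaml` manifest.
#' @return A `wf_snapshot_manifest` object.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path))
    stop("snapshot manifest not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  structure(list(case_name = doc$case_name, created_at = doc$created_at,
                 entries = doc$entries %||% list()),
            class = "wf_snapshot_manifest")
}

#' Validate current outputs against a recorded snapshot
#'
#' Produces one result per manifest entry: pass iff the file's current
#' digest equals the recorded one.  A recorded file now missing from
#' `output_dir` is a content change and therefore a fail.  Files present
#' in `output_dir` but absent from the manifest are ignored.
#'
#' @param manifest A `wf_snapshot_manifest` object or a path to one.
#' @param output_dir Directory holding the outputs to validate.
#' @return List of [assertion_result()], in manifest-entry order.
#' @export
assert_snapshot <- function(manifest, output_dir) {
  if (is.character(manifest)) manifest <- read_snapshot(manifest)
  stopifnot(inherits(manifest, "wf_snapshot_manifest"))
  results <- vector("list", length(manifest$entries))
  rels <- names(manifest$entries)
  for (i in seq_along(manifest$entries)) {
    entry <- manifest$entries[[i]]
    path <- file.path(output_dir, rels[i])
    results[[i]] <- if (!file.exists(path)) {
      assertion_result("fail", sprintf(
        "recorded output '%s' is missing", rels[i]), index = i)
    } else {
      current <- compute_checksum(path, entry$algorithm)
      if (identical(current, entry$digest))
        assertion_result("pass", sprintf(
          "'%s' matches recorded %s digest", rels[i], entry$algorithm),
          index = i)
      else
        assertion_result("fail", sprintf(
          "'%s' changed: recorded %s, now %s", rels[i], entry$digest,
          current), index = i)
    }
  }
  results
}

# Path of `path` relative to directory `base` (both made absolute first).
.wf_relpath <- function(path, base) {
  p <- normalizePath(path, winslash = "/", mustWork = FALSE)
  b <- normalizePath(base, winslash = "/", mustWork = FALSE)
  sub("^/", "", sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", b)),
                    "", p))
}

#' Dispatch a single assertion spec against resolved outputs
#'
#' Resolves the spec's `actual` pattern under `output_dir` and runs the
#' checksum or script comparison it declares.
#'
#' @param spec An [assertion_spec()].
#' @param output_dir The case's effective output directory.
#' @param index Ordinal of the spec within its case, recorded on the
#'   result.
#' @return An [assertion_result()].
#' @export
run_assertion <- function(spec, output_dir, index = NA_integer_) {
  actual <- tryCatch(resolve_actual(spec$actual, output_dir),
                     error = function(e) e)
  if (inherits(actual, "error")) {
    result <- assertion_result("error", conditionMessage(actual))
  } else {
    result <- switch(spec$method,
      checksum = assert_checksum(actual, spec$expect, spec$algorithm),
      script   = assert_script(spec$script, actual, spec$expect),
      assertion_result("error",
                       paste0("unsupported method: ", spec$method))
    )
  }
  result$index <- index
  result
}
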