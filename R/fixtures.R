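# Fixture generators: a stub workflow engine, synthetic VCFs, and seeded
# random files.  Everything the harness's own test suite needs is built by
# these at run time — no workflow engine, JVM or dataset required.

#' Declare the behaviour of a stub engine
#'
#' @param exit_code Exit status the stub terminates with.
#' @param outputs Named list mapping output-relative file paths to literal
#'   content strings the stub writes under the output directory it is
#'   handed.  Paths must be relative with no upward traversal.
#' @param echo_args Record the received argv (one token per line) into
#'   `<stub path>.argv`, for command-construction tests.
#' @return An object of class `wf_stub_behavior`.
#' @export
stub_behavior <- function(exit_code = 0L, outputs = list(),
                          echo_args = FALSE) {
  if (length(outputs) > 0) {
    bad <- grepl("^/|(^|/)\\.\\.(/|$)", names(outputs))
    if (any(bad))
      stop("stub output paths must be relative without '..': ",
           paste(names(outputs)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(exit_code = as.integer(exit_code), outputs = outputs,
                 echo_args = isTRUE(echo_args)),
            class = "wf_stub_behavior")
}

# Single-quote a string for POSIX sh.
.wf_sh_quote <- function(x) paste0("'", gsub("'", "'\\\\''", x), "'")

#' Generate a stub workflow engine
#'
#' Writes a portable POSIX `sh` script that accepts the engine command
#' surface emitted by [build_engine_command()] (`-c`, `run`, `-profile`,
#' `-params-file`, `--<param> <value>`, `-w`), takes the value following
#' any `--`-prefixed token as the output directory, writes the declared
#' output files under it, optionally records its argv, and exits with the
#' declared code.  No toolchain, JVM or network is needed.
#'
#' @param behavior A [stub_behavior()].
#' @param dest Directory to write the stub into.
#' @param name File name for the stub executable.
#' @return Path to the executable stub; its argv capture file (when
#'   `echo_args`) is `<path>.argv`.
#' @export
make_stub_engine <- function(behavior, dest, name = "stub-engine") {
  stopifnot(inherits(behavior, "wf_stub_behavior"))
  if (!dir.exists(dest) &&
      !dir.create(dest, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create stub destination: ", dest, call. = FALSE)
  path <- file.path(dest, name)
  argv_file <- paste0(path, ".argv")

  # The capture file accumulates argv across invocations (one token per
  # line); generating the stub resets it, so a whole suite run can be
  # inspected from one file.
  if (behavior$echo_args) file.create(argv_file)
  lines <- c("#!/bin/sh", "out=''", "prev=''")
  lines <- c(lines,
    'for a in "$@"; do',
    if (behavior$echo_args)
      paste0('  printf \'%s\\n\' "$a" >> ', .wf_sh_quote(argv_file)),
    '  case "$prev" in --*) out="$a";; esac',
    '  prev="$a"',
    "done")
  if (length(behavior$outputs) > 0) {
    lines <- c(lines, 'if [ -n "$out" ]; then', '  mkdir -p "$out"')
    for (rel in names(behavior$outputs)) {
      if (grepl("/", rel))
        lines <- c(lines, paste0('  mkdir -p "$out"/',
                                 .wf_sh_quote(dirname(rel))))
      lines <- c(lines, paste0("  printf '%s' ",
                               .wf_sh_quote(behavior$outputs[[rel]]),
                               ' > "$out"/', .wf_sh_quote(rel)))
    }
    lines <- c(lines, "fi")
  }
  lines <- c(lines, paste0("exit ", behavior$exit_code))

  writeLines(lines, path)
  Sys.chmod(path, "0755")
  path
}

#' Write a small synthetic VCF
#'
#' Writes the given meta lines (each prefixed `##` unless already
#' `#`-prefixed), a `#CHROM` column header line, then the record lines,
#' optionally gzip-compressed.
#'
#' @param records Character vector of tab-delimited variant record lines.
#' @param header_lines Character vector of meta-information lines.
#' @param dest Destination file path.
#' @param gzip Compress the output?
#' @return `dest`, invisibly.
#' @export
make_vcf <- function(records, header_lines = "##fileformat=VCFv4.2",
                     dest = tempfile(fileext = ".vcf"), gzip = FALSE) {
  headers <- ifelse(startsWith(header_lines, "#"), header_lines,
                    paste0("##", header_lines))
  chrom_line <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  con <- if (gzip) gzfile(dest, "wb") else file(dest, "wb")
  on.exit(close(con))
  writeLines(c(headers, chrom_line, records), con)
  invisible(dest)
}

#' Write a deterministic pseudo-random file
#'
#' Produces `size` bytes drawn from a local RNG stream seeded with `seed`;
#' the same seed and size always yield a byte-identical file.  The
#' session's `.Random.seed` is left untouched.
#'
#' @param seed Integer seed.
#' @param size Number of bytes.
#' @param dest Destination file path.
#' @return `dest`, invisibly.
#' @export
make_random_file <- function(seed, size,
                             dest = tempfile(fileext = ".bin")) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  bytes <- as.raw(sample.int(256L, size, replace = TRUE) - 1L)
  writeBin(bytes, dest)
  invisible(dest)
}

#' Generate random variant record lines
#'
#' Convenience generator for comparator tests: coordinate-sorted,
#' tab-delimited VCF record lines with random alleles.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param chrom Chromosome name used for every record.
#' @return Character vector of `n` record lines.
#' @export
make_vcf_records <- function(n, seed = 1L, chrom = "chr21") {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pos <- sort(sample.int(1e7L, n))
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                character(1))
  sprintf("%s\t%d\t.\t%s\t%s\t%.1f\tPASS\tDP=%d", chrom, pos, ref, alt,
          stats::runif(n, 10, 99), sample.int(200L, n, replace = TRUE))
}
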