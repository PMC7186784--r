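#' @importFrom rlang abort warn .data
NULL

# Write a text file atomically: write to a sibling temp file, then rename.
atomic_write_lines <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!file.rename(tmp, path)) {
    abort(paste0("cannot write to '", path, "'"), class = "bsyn_io_error")
  }
  invisible(path)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(
      paste0("`", name, "` must be a single integer >= ", min),
      class = "bsyn_parameter_error"
    )
  }
  invisible(as.integer(x))
}

# Integer formatting with thousands separators, as in assembly reports.
fmt_int <- function(x) formatC(round(x), format = "d", big.mark = ",")
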