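#' Read a FASTA file into a table of sequence records
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file and returns one
#' row per scaffold, in file order. The header line is split into `id` (the
#' first whitespace-delimited token) and `description` (the remainder, possibly
#' empty). Residue case is preserved: soft-masked lowercase bases stay
#' lowercase, and all downstream counting in this package folds case instead.
#'
#' @param path Path to a FASTA file, plain or gzipped.
#' @return A tibble with columns `id`, `description`, `seq`, one row per
#'   record, in the order the records appear in the file.
#' @details Duplicate record ids are an error, not a silent overwrite:
#'   coordinate lookups downstream (BUSCO placements, Circos karyotypes)
#'   require unique scaffold identifiers. An empty file yields a zero-row
#'   tibble with a warning.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: '", path, "'"), class = "bsyn_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      bad <- first_malformed_fasta_line(path)
      abort(
        paste0(
          "malformed FASTA in '", path, "'",
          if (!is.na(bad)) paste0(" at line ", bad) else "",
          ": ", conditionMessage(e)
        ),
        class = "bsyn_parse_error"
      )
    }
  )
  if (length(set) == 0L) {
    warn(paste0("FASTA file '", path, "' contains no records"))
    return(tibble::tibble(id = character(), description = character(), seq = character()))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort(
      paste0("duplicate sequence id(s) in '", path, "': ", paste(dup, collapse = ", ")),
      class = "bsyn_integrity_error"
    )
  }
  if (any(id == "" | is.na(id))) {
    abort(paste0("empty sequence id in '", path, "'"), class = "bsyn_parse_error")
  }
  tibble::tibble(id = id, description = description, seq = as.character(unname(set)))
}

# Locate the first line of a FASTA file that cannot start a record: content
# before the first '>' header, or a bare '>' with no id.
first_malformed_fasta_line <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  i <- 0L
  seen_header <- FALSE
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NA_integer_)
    i <- i + 1L
    if (grepl("^\\s*$", line) || grepl("^;", line)) next
    if (startsWith(line, ">")) {
      if (grepl("^>\\s*$", line)) return(i)
      seen_header <- TRUE
    } else if (!seen_header) {
      return(i)
    }
  }
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble as returned by [read_fasta()] (columns `id`,
#'   `description`, `seq`).
#' @param path Output path. A `.gz` suffix triggers gzip compression.
#' @param line_width Positive integer; residues per sequence line.
#' @return The path, invisibly.
#' @details `read_fasta(write_fasta(x))` reproduces ids, descriptions and
#'   sequences exactly; only line wrapping may differ from the original file.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  validate_seq_records(records)
  stopifnot_scalar_count(line_width, "line_width")
  headers <- ifelse(
    records$description == "",
    records$id,
    paste(records$id, records$description)
  )
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  ok <- tryCatch(
    {
      Biostrings::writeXStringSet(
        set, path,
        width = as.integer(line_width),
        compress = grepl("\\.gz$", path)
      )
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) {
    abort(
      paste0("cannot write FASTA to '", path, "': ", conditionMessage(ok)),
      class = "bsyn_io_error"
    )
  }
  invisible(path)
}

# Shared validity checks for the record tibble used across the package.
validate_seq_records <- function(records, arg = "records") {
  if (!is.data.frame(records) ||
      !all(c("id", "description", "seq") %in% names(records))) {
    abort(
      paste0("`", arg, "` must be a data frame with columns id, description, seq"),
      class = "bsyn_parameter_error"
    )
  }
  if (nrow(records) == 0L) return(invisible(records))
  if (any(records$id == "" | is.na(records$id)) || any(grepl("\\s", records$id))) {
    abort("sequence ids must be nonempty and contain no whitespace",
          class = "bsyn_integrity_error")
  }
  if (anyDuplicated(records$id)) {
    abort("sequence ids must be unique", class = "bsyn_integrity_error")
  }
  if (any(nchar(records$seq) < 1L) || any(grepl("\\s", records$seq))) {
    abort("sequences must be nonempty and contain no whitespace",
          class = "bsyn_integrity_error")
  }
  invisible(records)
}

#' Scaffold lengths of a record set
#'
#' @param records Record tibble from [read_fasta()], or a path to a 2-column
#'   TSV (`id`, `length`).
#' @return Named integer-valued numeric vector of scaffold lengths.
#' @export
scaffold_lengths <- function(records) {
  if (is.character(records) && length(records) == 1L) {
    tab <- utils::read.table(records, sep = "\t", header = FALSE,
                             col.names = c("id", "length"),
                             colClasses = c("character", "numeric"))
    if (anyDuplicated(tab$id)) {
      abort("duplicate ids in scaffold length table", class = "bsyn_integrity_error")
    }
    return(stats::setNames(tab$length, tab$id))
  }
  validate_seq_records(records)
  stats::setNames(nchar(records$seq), records$id)
}
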