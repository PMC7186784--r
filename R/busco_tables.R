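BUSCO_STATUSES <- c("Complete", "Duplicated", "Fragmented", "Missing")

#' Parse a BUSCO full-table file
#'
#' Reads the `full_table*.tsv` output of BUSCO, autodetecting the column
#' layout: the v2/v3 dialect (`id, Status, Contig, Start, End, Score, Length`)
#' and the later dialects that insert a `Strand` column after `End` (and may
#' append OrthoDB URL / description columns, which are ignored). `Missing`
#' rows carry no placement. Rows whose `Start` exceeds `End` (minus-strand
#' predictions in some BUSCO builds) are normalized by swapping, with a
#' message.
#'
#' @param path Path to a BUSCO full table (TSV, `#` comment lines allowed).
#' @return A tibble with one row per table row: `busco_id`, `status`,
#'   `scaffold_id`, `start`, `end`, `strand`, `score`, `length`,
#'   `source_direction` (initialized to `"forward"`). Coordinates are 1-based
#'   inclusive; placement fields are `NA` for `Missing` rows.
#' @export
parse_full_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BUSCO table not found: '", path, "'"), class = "bsyn_io_error")
  }
  raw <- readLines(path, warn = FALSE)
  line_no <- seq_along(raw)
  keep <- !grepl("^\\s*#", raw) & !grepl("^\\s*$", raw)
  raw <- raw[keep]
  line_no <- line_no[keep]
  if (length(raw) == 0L) {
    return(empty_busco_tbl())
  }
  fields <- stringi::stri_split_fixed(raw, "\t")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    abort(
      paste0("unrecognized BUSCO table row at line ", line_no[which(nf < 2L)[1]],
             ": fewer than 2 columns"),
      class = "bsyn_dialect_error"
    )
  }

  status <- vapply(fields, `[[`, character(1), 2)
  bad_status <- !status %in% BUSCO_STATUSES
  if (any(bad_status)) {
    abort(
      paste0("unknown BUSCO status '", status[which(bad_status)[1]],
             "' at line ", line_no[which(bad_status)[1]]),
      class = "bsyn_parse_error"
    )
  }
  placed <- status != "Missing"
  if (any(placed & nf < 5L)) {
    i <- which(placed & nf < 5L)[1]
    abort(
      paste0("unrecognized column layout at line ", line_no[i],
             ": placed BUSCO with fewer than 5 columns"),
      class = "bsyn_dialect_error"
    )
  }

  # Dialect: the later table layouts put a strand symbol in column 6.
  col6 <- vapply(fields, function(f) if (length(f) >= 6L) f[[6]] else NA_character_,
                 character(1))
  has_strand <- any(placed & col6 %in% c("+", "-"))

  get_col <- function(j) {
    vapply(fields, function(f) if (length(f) >= j) f[[j]] else NA_character_,
           character(1))
  }
  num_col <- function(values, what) {
    suppress <- values %in% c("", "N/A", "NA")
    out <- suppressWarnings(as.numeric(values))
    bad <- placed & is.na(out) & !is.na(values) & !suppress
    if (any(bad)) {
      i <- which(bad)[1]
      abort(
        paste0("non-numeric ", what, " '", values[i], "' at line ", line_no[i]),
        class = "bsyn_parse_error"
      )
    }
    out[suppress] <- NA_real_
    out
  }

  start <- num_col(get_col(4), "start coordinate")
  end <- num_col(get_col(5), "end coordinate")
  if (has_strand) {
    strand <- get_col(6)
    score <- num_col(get_col(7), "score")
    len <- num_col(get_col(8), "length")
  } else {
    strand <- rep(NA_character_, length(fields))
    score <- num_col(get_col(6), "score")
    len <- num_col(get_col(7), "length")
  }

  swapped <- placed & !is.na(start) & !is.na(end) & start > end
  if (any(swapped)) {
    message(sum(swapped), " row(s) with start > end normalized by swapping")
    tmp <- start[swapped]
    start[swapped] <- end[swapped]
    end[swapped] <- tmp
  }

  tbl <- tibble::tibble(
    busco_id = vapply(fields, `[[`, character(1), 1),
    status = status,
    scaffold_id = ifelse(placed, get_col(3), NA_character_),
    start = ifelse(placed, start, NA_real_),
    end = ifelse(placed, end, NA_real_),
    strand = ifelse(placed, strand, NA_character_),
    score = ifelse(placed, score, NA_real_),
    length = ifelse(placed, len, NA_real_),
    source_direction = "forward"
  )
  validate_busco_tbl(tbl)
  tbl
}

empty_busco_tbl <- function() {
  tibble::tibble(
    busco_id = character(), status = character(), scaffold_id = character(),
    start = numeric(), end = numeric(), strand = character(),
    score = numeric(), length = numeric(), source_direction = character()
  )
}

validate_busco_tbl <- function(tbl, arg = "records") {
  need <- c("busco_id", "status", "scaffold_id", "start", "end")
  if (!is.data.frame(tbl) || !all(need %in% names(tbl))) {
    abort(paste0("`", arg, "` must be a BUSCO record tibble (see parse_full_table)"),
          class = "bsyn_parameter_error")
  }
  if (!all(tbl$status %in% BUSCO_STATUSES)) {
    abort("invalid BUSCO status values", class = "bsyn_parse_error")
  }
  placed <- tbl$status != "Missing"
  if (any(placed & (is.na(tbl$scaffold_id) | is.na(tbl$start) | is.na(tbl$end)))) {
    abort("placed BUSCO records require scaffold_id, start and end",
          class = "bsyn_integrity_error")
  }
  if (any(placed & tbl$start > tbl$end, na.rm = TRUE)) {
    abort("BUSCO records must satisfy start <= end", class = "bsyn_integrity_error")
  }
  invisible(tbl)
}

#' Status summary of a BUSCO record set
#'
#' Counts distinct ortholog ids per status. `Duplicated` orthologs appear as
#' multiple rows in a full table but are counted once, so the four status
#' counts always partition `n_total`.
#'
#' @param records BUSCO record tibble.
#' @return A tibble with one row: `n_complete`, `n_duplicated`,
#'   `n_fragmented`, `n_missing`, `n_total`.
#' @export
busco_summary <- function(records) {
  validate_busco_tbl(records)
  per_id <- dplyr::distinct(records, .data$busco_id, .data$status)
  if (anyDuplicated(per_id$busco_id)) {
    abort("an ortholog id carries more than one status", class = "bsyn_integrity_error")
  }
  n <- function(s) sum(per_id$status == s)
  tibble::tibble(
    n_complete = n("Complete"),
    n_duplicated = n("Duplicated"),
    n_fragmented = n("Fragmented"),
    n_missing = n("Missing"),
    n_total = nrow(per_id)
  )
}

#' Remap placements from a reverse-complemented assembly to forward coordinates
#'
#' A feature at `[start, end]` on the reverse complement of a scaffold of
#' length `L` lies at `[L - end + 1, L - start + 1]` on the forward strand.
#' The mapping preserves interval length and is an involution.
#'
#' @param records BUSCO record tibble (placed rows are remapped; `Missing`
#'   rows pass through).
#' @param scaffold_lengths Named vector of scaffold lengths (names are the
#'   scaffold ids of the records), e.g. from [scaffold_lengths()].
#' @return The records with remapped `start`/`end` and `source_direction`
#'   set to `"revcomp"` for remapped rows.
#' @export
remap_revcomp <- function(records, scaffold_lengths) {
  validate_busco_tbl(records)
  placed <- records$status != "Missing"
  if (!any(placed)) return(records)
  ids <- records$scaffold_id[placed]
  unknown <- setdiff(unique(ids), names(scaffold_lengths))
  if (length(unknown)) {
    abort(paste0("no scaffold length for: ", paste(unknown, collapse = ", ")),
          class = "bsyn_coordinate_error")
  }
  L <- unname(scaffold_lengths[ids])
  if (any(records$end[placed] > L)) {
    abort("BUSCO placement end exceeds scaffold length",
          class = "bsyn_coordinate_error")
  }
  new_start <- L - records$end[placed] + 1
  new_end <- L - records$start[placed] + 1
  records$start[placed] <- new_start
  records$end[placed] <- new_end
  records$source_direction[placed] <- ifelse(
    records$source_direction[placed] == "revcomp", "forward", "revcomp"
  )
  records
}

status_rank <- function(status) match(status, BUSCO_STATUSES)

#' Merge forward and reverse-complement BUSCO runs
#'
#' Running BUSCO a second time on the reverse complement of an assembly
#' rescues orthologs the forward run missed. Per ortholog id, the record with
#' the better status is kept under the precedence
#' `Complete > Duplicated > Fragmented > Missing`; on a status tie the
#' forward record is kept. Reverse-complement placements are remapped to
#' forward coordinates before merging, so merged coordinates are all on the
#' forward assembly.
#'
#' @param forward BUSCO record tibble from the forward run.
#' @param revcomp BUSCO record tibble from the reverse-complement run
#'   (coordinates as reported on the reverse-complemented assembly).
#' @param scaffold_lengths Named scaffold length vector for remapping.
#' @return Merged BUSCO record tibble over the union of ortholog ids; ids
#'   present in only one run are treated as `Missing` in the other, with a
#'   warning.
#' @export
merge_runs <- function(forward, revcomp, scaffold_lengths) {
  validate_busco_tbl(forward, "forward")
  validate_busco_tbl(revcomp, "revcomp")
  revcomp <- remap_revcomp(revcomp, scaffold_lengths)

  ids_f <- unique(forward$busco_id)
  ids_r <- unique(revcomp$busco_id)
  only_f <- setdiff(ids_f, ids_r)
  only_r <- setdiff(ids_r, ids_f)
  if (length(only_f) || length(only_r)) {
    warn(paste0(
      length(only_f) + length(only_r),
      " ortholog id(s) present in one run only; treated as Missing in the other"
    ))
  }
  missing_row <- function(ids) {
    if (!length(ids)) return(empty_busco_tbl())
    tibble::tibble(
      busco_id = ids, status = "Missing", scaffold_id = NA_character_,
      start = NA_real_, end = NA_real_, strand = NA_character_,
      score = NA_real_, length = NA_real_, source_direction = "forward"
    )
  }
  forward <- dplyr::bind_rows(forward, missing_row(only_r))
  revcomp <- dplyr::bind_rows(revcomp, missing_row(only_f))

  best_status <- function(tbl) {
    s <- dplyr::summarise(
      dplyr::group_by(tbl, .data$busco_id),
      rank = min(status_rank(.data$status)), .groups = "drop"
    )
    stats::setNames(s$rank, s$busco_id)
  }
  rank_f <- best_status(forward)
  rank_r <- best_status(revcomp)
  all_ids <- names(rank_f)
  take_rev <- rank_r[all_ids] < rank_f[all_ids]
  merged <- dplyr::bind_rows(
    forward[forward$busco_id %in% all_ids[!take_rev], ],
    revcomp[revcomp$busco_id %in% all_ids[take_rev], ]
  )
  merged <- merged[order(merged$busco_id, merged$start), ]
  validate_busco_tbl(merged)
  merged
}

#' Extract the single-copy ortholog placement set
#'
#' Keeps only `Complete` orthologs -- the single-copy anchors used for
#' synteny. `Duplicated`, `Fragmented` and `Missing` records are excluded:
#' a duplicated ortholog has no unique placement and cannot anchor a
#' one-to-one link.
#'
#' @param records Merged BUSCO record tibble.
#' @return Tibble of placements: `busco_id`, `chromosome_id`, `start`, `end`,
#'   `source_direction`, exactly one row per ortholog id.
#' @export
extract_sco_set <- function(records) {
  validate_busco_tbl(records)
  complete <- records[records$status == "Complete", ]
  if (anyDuplicated(complete$busco_id)) {
    dup <- unique(complete$busco_id[duplicated(complete$busco_id)])
    abort(
      paste0("multiple Complete records for ortholog(s): ",
             paste(utils::head(dup, 5), collapse = ", ")),
      class = "bsyn_integrity_error"
    )
  }
  tibble::tibble(
    busco_id = complete$busco_id,
    chromosome_id = complete$scaffold_id,
    start = complete$start,
    end = complete$end,
    source_direction = complete$source_direction
  )
}
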