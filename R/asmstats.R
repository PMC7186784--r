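#' Decompose a scaffold into contigs at N-gap runs
#'
#' A contig is a maximal span of the scaffold containing no run of `min_gap`
#' or more consecutive `N` (case-insensitive); the separating N-runs of length
#' `>= min_gap` are gaps. Shorter N-runs are retained inside contigs.
#' Leading or trailing qualifying N-runs are gaps that bound no contig, so no
#' zero-length contig is ever emitted; their bases still count toward the
#' scaffold total.
#'
#' @param record One-row record tibble (see [read_fasta()]), or a single
#'   sequence string (then `scaffold_id` defaults to `"seq"`).
#' @param min_gap Minimum N-run length that counts as a gap (default 10).
#' @return A list with `contigs` (tibble: `scaffold_id`, `start`, `end`,
#'   `length`; 1-based inclusive coordinates) and `gaps` (integer vector of
#'   gap lengths).
#' @examples
#' split_into_contigs(paste0("ACGT", strrep("N", 10), "ACGT"))
#' @export
split_into_contigs <- function(record, min_gap = 10L) {
  stopifnot_scalar_count(min_gap, "min_gap")
  if (is.character(record)) {
    record <- tibble::tibble(id = "seq", description = "", seq = record)
  }
  validate_seq_records(record)
  if (nrow(record) != 1L) {
    abort("`record` must contain exactly one sequence; see assembly_report() for sets",
          class = "bsyn_parameter_error")
  }
  res <- locate_contigs(record$seq, min_gap)
  n <- nrow(res$contigs)
  tibble_contigs <- tibble::tibble(
    scaffold_id = rep(record$id, n),
    start = res$contigs$start,
    end = res$contigs$end,
    length = res$contigs$end - res$contigs$start + 1L
  )
  list(contigs = tibble_contigs, gaps = res$gap_lengths)
}

# Core span arithmetic for one sequence string. Returns contig start/end and
# gap lengths; gaps are the N-runs of >= min_gap, contigs the complement.
locate_contigs <- function(seq, min_gap) {
  L <- nchar(seq)
  m <- stringi::stri_locate_all_regex(
    seq, paste0("[Nn]{", min_gap, ",}")
  )[[1]]
  if (is.na(m[1, 1])) {
    return(list(
      contigs = data.frame(start = 1L, end = L),
      gap_lengths = integer()
    ))
  }
  gap_start <- m[, 1]
  gap_end <- m[, 2]
  # Contig candidates are the complement intervals; drop empty ones that
  # arise from leading/trailing/adjacent gaps.
  cstart <- c(1L, gap_end + 1L)
  cend <- c(gap_start - 1L, L)
  keep <- cstart <= cend
  list(
    contigs = data.frame(start = as.integer(cstart[keep]), end = as.integer(cend[keep])),
    gap_lengths = as.integer(gap_end - gap_start + 1L)
  )
}

#' Nx / Lx contiguity series
#'
#' Sorts lengths in descending order; `Nx` is the length of the sequence at
#' which the cumulative length first reaches `ceiling(x% of total)`, and `Lx`
#' is the 1-based rank of that sequence. Ties in length are broken by the
#' earlier (larger-length) rank.
#'
#' @param lengths Positive sequence lengths (at least one).
#' @param x_values Percentages to evaluate (default 50, 60, 70, 80, 90).
#' @return Tibble with columns `x`, `n_length`, `l_count`.
#' @examples
#' nx_series(c(8, 5, 4, 2, 1)) # N50 = 5 at L50 = 2
#' @export
nx_series <- function(lengths, x_values = c(50, 60, 70, 80, 90)) {
  if (length(lengths) == 0L) {
    abort("`lengths` must contain at least one value", class = "bsyn_parameter_error")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("`lengths` must be positive and finite", class = "bsyn_parameter_error")
  }
  sorted <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(as.numeric(sorted))
  total <- csum[length(csum)]
  idx <- vapply(
    x_values,
    function(x) which(csum >= ceiling(x / 100 * total))[1],
    integer(1)
  )
  tibble::tibble(
    x = as.integer(x_values),
    n_length = sorted[idx],
    l_count = as.integer(idx)
  )
}

#' Base composition of a record set
#'
#' Case-insensitive counts of A, C, G, T, N and everything else
#' (IUPAC ambiguity codes and any other residue), with percentages over the
#' total residue count including N.
#'
#' @param records Record tibble from [read_fasta()], or a character vector of
#'   sequences.
#' @return Tibble with columns `base` (`A`, `C`, `G`, `T`, `N`, `other`),
#'   `count`, `pct`.
#' @export
composition <- function(records) {
  seqs <- if (is.character(records)) records else {
    validate_seq_records(records)
    records$seq
  }
  if (length(seqs) == 0L) {
    abort("`records` must contain at least one sequence", class = "bsyn_parameter_error")
  }
  counts <- vapply(
    c(A = "[Aa]", C = "[Cc]", G = "[Gg]", T = "[Tt]", N = "[Nn]"),
    function(cls) sum(stringi::stri_count_charclass(seqs, cls)),
    numeric(1)
  )
  total <- sum(nchar(seqs))
  counts <- c(counts, other = total - sum(counts))
  tibble::tibble(
    base = c("A", "C", "G", "T", "N", "other"),
    count = unname(counts),
    pct = unname(100 * counts / total)
  )
}

# Count/size/threshold/mean/median summary shared by the scaffold and contig
# levels. Medians over an even count take the lower central value, matching
# the integer medians of Assemblathon-style reports.
length_summary <- function(lengths) {
  thresholds <- c(`1K` = 1e3, `10K` = 1e4, `100K` = 1e5, `1M` = 1e6, `10M` = 1e7)
  n <- length(lengths)
  sorted <- sort(lengths)
  list(
    count = n,
    total_size = sum(as.numeric(lengths)),
    longest = max(lengths),
    shortest = min(lengths),
    thresholds = tibble::tibble(
      threshold = names(thresholds),
      n_above = vapply(thresholds, function(t) sum(lengths > t), numeric(1)),
      pct_above = vapply(thresholds, function(t) 100 * sum(lengths > t) / n, numeric(1))
    ),
    mean = mean(lengths),
    median = sorted[floor((n + 1) / 2)]
  )
}

#' Full Assemblathon-style assembly report
#'
#' Computes the complete scaffold- and contig-level statistic set for an
#' assembly: counts, total sizes, longest/shortest, counts above fixed size
#' thresholds, mean and median, the N50-N90 / L50-L90 series, base
#' composition, and the scaffold/contig bookkeeping (contigs in vs not in
#' scaffolds, percentage of contig bases in scaffolded scaffolds, mean
#' contigs per scaffold, mean gap length).
#'
#' A scaffold containing at least one qualifying gap (N-run of `>= min_gap`)
#' is "scaffolded" and its contigs count as "in scaffolds"; a gap-free
#' scaffold is itself one "unscaffolded" contig.
#'
#' @param records Record tibble from [read_fasta()].
#' @param min_gap Minimum N-run length that counts as a gap (default 10).
#' @return An object of class `assembly_report`; see
#'   [format.assembly_report()] for the plain-text rendering and
#'   [write_report_json()] / [write_report_tsv()] for machine-readable twins.
#' @export
assembly_report <- function(records, min_gap = 10L) {
  validate_seq_records(records)
  if (nrow(records) == 0L) {
    abort("`records` must contain at least one sequence", class = "bsyn_parameter_error")
  }
  stopifnot_scalar_count(min_gap, "min_gap")

  scaffold_lens <- nchar(records$seq)
  split <- lapply(records$seq, locate_contigs, min_gap = min_gap)
  n_contigs_per_scaffold <- vapply(split, function(s) nrow(s$contigs), integer(1))
  gap_lengths <- unlist(lapply(split, `[[`, "gap_lengths"))
  has_gap <- vapply(split, function(s) length(s$gap_lengths) > 0L, logical(1))

  contig_tbl <- tibble::tibble(
    scaffold_id = rep(records$id, n_contigs_per_scaffold),
    start = unlist(lapply(split, function(s) s$contigs$start)),
    end = unlist(lapply(split, function(s) s$contigs$end)),
    in_scaffold = rep(has_gap, n_contigs_per_scaffold)
  )
  contig_tbl$length <- contig_tbl$end - contig_tbl$start + 1L

  scaffold_comp <- composition(records)
  # Contig composition follows from the scaffold composition minus the gap
  # bases, which are all N.
  total_gap <- sum(as.numeric(gap_lengths))
  contig_comp <- scaffold_comp
  contig_comp$count[contig_comp$base == "N"] <-
    contig_comp$count[contig_comp$base == "N"] - total_gap
  contig_comp$pct <- 100 * contig_comp$count / sum(contig_comp$count)

  contig_bases <- sum(as.numeric(contig_tbl$length))
  scaffolded_bases <- sum(as.numeric(contig_tbl$length[contig_tbl$in_scaffold]))

  out <- list(
    min_gap = as.integer(min_gap),
    scaffold = length_summary(scaffold_lens),
    contig = length_summary(contig_tbl$length),
    scaffold_nx = nx_series(scaffold_lens),
    contig_nx = nx_series(contig_tbl$length),
    scaffold_composition = scaffold_comp,
    contig_composition = contig_comp,
    pct_in_scaffolded_contigs = 100 * scaffolded_bases / contig_bases,
    pct_in_unscaffolded_contigs = 100 * (contig_bases - scaffolded_bases) / contig_bases,
    mean_contigs_per_scaffold = nrow(contig_tbl) / nrow(records),
    mean_gap_length = if (length(gap_lengths)) mean(gap_lengths) else NA_real_,
    n_gaps = length(gap_lengths),
    total_gap_length = total_gap,
    n_contigs_in_scaffolds = sum(contig_tbl$in_scaffold),
    n_contigs_not_in_scaffolds = sum(!contig_tbl$in_scaffold),
    contigs = contig_tbl
  )
  class(out) <- "assembly_report"
  out
}

report_rows <- function(report) {
  lvl_rows <- function(s, nx, comp, level) {
    Level <- paste0(toupper(substring(level, 1, 1)), substring(level, 2))
    rows <- list(
      c(paste0("Number of ", level, "s"), fmt_int(s$count), ""),
      c(paste0("Total size of ", level, "s"), fmt_int(s$total_size), ""),
      c(paste0("Longest ", level), fmt_int(s$longest), ""),
      c(paste0("Shortest ", level), fmt_int(s$shortest), "")
    )
    for (i in seq_len(nrow(s$thresholds))) {
      rows <- c(rows, list(c(
        paste0("Number of ", level, "s >", s$thresholds$threshold[i], " nt"),
        fmt_int(s$thresholds$n_above[i]),
        sprintf("%.2f%%", s$thresholds$pct_above[i])
      )))
    }
    rows <- c(rows, list(
      c(paste0("Mean ", level, " size"), fmt_int(round(s$mean)), ""),
      c(paste0("Median ", level, " size"), fmt_int(s$median), "")
    ))
    for (i in seq_len(nrow(nx))) {
      rows <- c(rows, list(c(
        paste0("N", nx$x[i], " ", level, " length"), fmt_int(nx$n_length[i]),
        paste0("L", nx$x[i], " ", level, " count ", fmt_int(nx$l_count[i]))
      )))
    }
    for (i in seq_len(nrow(comp))) {
      base <- comp$base[i]
      lab <- if (base == "other") "non-ACGTN" else base
      rows <- c(rows, list(c(
        paste0(Level, " %", lab),
        sub("\\.?0+$", "", sprintf("%.2f", comp$pct[i])),
        paste0("Number of ", lab, " ", fmt_int(comp$count[i]))
      )))
    }
    rows
  }
  rows <- lvl_rows(report$scaffold, report$scaffold_nx, report$scaffold_composition, "scaffold")
  rows <- c(rows, list(
    c("Percentage of assembly in scaffolded contigs",
      sprintf("%.2f", report$pct_in_scaffolded_contigs), ""),
    c("Percentage of assembly in unscaffolded contigs",
      sprintf("%.2f", report$pct_in_unscaffolded_contigs), ""),
    c("Average number of contigs per scaffold",
      sprintf("%.1f", report$mean_contigs_per_scaffold), ""),
    c(sprintf("Average length of break (>=%d N) between contigs in scaffold", report$min_gap),
      if (is.na(report$mean_gap_length)) "0" else fmt_int(round(report$mean_gap_length)), ""),
    c("Number of contigs in scaffolds", fmt_int(report$n_contigs_in_scaffolds), ""),
    c("Number of contigs not in scaffolds", fmt_int(report$n_contigs_not_in_scaffolds), "")
  ))
  rows <- c(rows, lvl_rows(report$contig, report$contig_nx, report$contig_composition, "contig"))
  rows
}

#' @exportS3Method base::format
format.assembly_report <- function(x, ...) {
  vapply(
    report_rows(x),
    function(r) paste(r[r != ""], collapse = "\t"),
    character(1)
  )
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write an assembly report as JSON
#'
#' @param report An `assembly_report` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$contigs <- NULL # per-contig spans are bulky; use the TSV twin for those
  atomic_write_lines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"),
    path
  )
}

#' Write an assembly report as two-to-three-column TSV
#'
#' @inheritParams write_report_json
#' @export
write_report_tsv <- function(report, path) {
  lines <- vapply(report_rows(report), function(r) paste(r, collapse = "\t"), character(1))
  atomic_write_lines(lines, path)
}
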