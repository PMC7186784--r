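#' Build synteny links from two single-copy ortholog sets
#'
#' One link per ortholog id Complete (single-copy) in both genomes, carrying
#' its placement coordinates on both sides. Ids present in only one genome
#' are dropped; their counts are attached as attributes `n_only_a` and
#' `n_only_b`.
#'
#' @param sco_a,sco_b Placement tibbles from [extract_sco_set()] for genomes
#'   A and B (unique `busco_id` per genome).
#' @return Tibble of links: `busco_id`, `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, ordered by (`chrom_a`, `start_a`,
#'   `busco_id`).
#' @export
build_links <- function(sco_a, sco_b) {
  validate_sco(sco_a, "sco_a")
  validate_sco(sco_b, "sco_b")
  a <- tibble::tibble(
    busco_id = sco_a$busco_id, chrom_a = sco_a$chromosome_id,
    start_a = sco_a$start, end_a = sco_a$end
  )
  b <- tibble::tibble(
    busco_id = sco_b$busco_id, chrom_b = sco_b$chromosome_id,
    start_b = sco_b$start, end_b = sco_b$end
  )
  links <- dplyr::inner_join(a, b, by = "busco_id")
  links <- links[order(links$chrom_a, links$start_a, links$busco_id), ]
  attr(links, "n_only_a") <- nrow(a) - nrow(links)
  attr(links, "n_only_b") <- nrow(b) - nrow(links)
  links
}

validate_sco <- function(sco, arg) {
  need <- c("busco_id", "chromosome_id", "start", "end")
  if (!is.data.frame(sco) || !all(need %in% names(sco))) {
    abort(paste0("`", arg, "` must be an SCO placement tibble (see extract_sco_set)"),
          class = "bsyn_parameter_error")
  }
  if (anyDuplicated(sco$busco_id)) {
    abort(paste0("duplicate busco_id in `", arg, "`: SCO sets are single-copy"),
          class = "bsyn_integrity_error")
  }
  invisible(sco)
}

validate_links <- function(links, arg = "links") {
  need <- c("busco_id", "chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
  if (!is.data.frame(links) || !all(need %in% names(links))) {
    abort(paste0("`", arg, "` must be a synteny link tibble (see build_links)"),
          class = "bsyn_parameter_error")
  }
  invisible(links)
}

#' Remove single relocations
#'
#' A "single relocation" is a chromosome pair supported by only one shared
#' ortholog: one gene moving on its own is not evidence of a chromosomal
#' rearrangement, so such links are removed before events are interpreted.
#' More generally, a link survives only if its (`chrom_a`, `chrom_b`) pair is
#' supported by at least `min_links` links.
#'
#' @param links Link tibble from [build_links()].
#' @param min_links Minimum supporting link count per chromosome pair
#'   (default 2; 1 disables filtering).
#' @return The surviving links; the number removed is attached as attribute
#'   `n_removed`.
#' @export
filter_single_relocations <- function(links, min_links = 2L) {
  validate_links(links)
  stopifnot_scalar_count(min_links, "min_links")
  if (nrow(links) == 0L) {
    attr(links, "n_removed") <- 0L
    return(links)
  }
  kept <- dplyr::mutate(
    dplyr::group_by(links, .data$chrom_a, .data$chrom_b),
    .n_pair = dplyr::n()
  )
  kept <- dplyr::ungroup(kept)
  keep <- kept$.n_pair >= min_links
  out <- links[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Chain links into syntenic blocks
#'
#' Links are sorted by (`chrom_a`, `start_a`); consecutive links sharing the
#' same (`chrom_a`, `chrom_b`) pair whose distance on genome A is at most
#' `max_gap_a` join one block. With the default unlimited gap, a block is
#' simply all links of one chromosome pair that are contiguous in A-order on
#' `chrom_a`. Every link belongs to exactly one block.
#'
#' @param links Link tibble (normally after [filter_single_relocations()]).
#' @param max_gap_a Maximum distance in bases between consecutive link starts
#'   on genome A within a block (default `Inf`).
#' @return Tibble of blocks: `block_id`, `chrom_a`, `chrom_b`, `n_links`,
#'   `start_a`, `end_a`, `start_b`, `end_b`, and a list-column `links` with
#'   the member links of each block, ordered by `start_a`.
#' @export
chain_blocks <- function(links, max_gap_a = Inf) {
  validate_links(links)
  if (!is.numeric(max_gap_a) || length(max_gap_a) != 1L || max_gap_a <= 0) {
    abort("`max_gap_a` must be a single positive number (Inf allowed)",
          class = "bsyn_parameter_error")
  }
  if (nrow(links) == 0L) {
    return(tibble::tibble(
      block_id = integer(), chrom_a = character(), chrom_b = character(),
      n_links = integer(), start_a = numeric(), end_a = numeric(),
      start_b = numeric(), end_b = numeric(), links = list()
    ))
  }
  links <- links[order(links$chrom_a, links$start_a, links$busco_id), ]
  new_block <- c(TRUE, (
    links$chrom_a[-1] != links$chrom_a[-nrow(links)] |
    links$chrom_b[-1] != links$chrom_b[-nrow(links)] |
    (links$start_a[-1] - links$start_a[-nrow(links)]) > max_gap_a
  ))
  links$block_id <- cumsum(new_block)
  blocks <- dplyr::summarise(
    dplyr::group_by(links, .data$block_id),
    chrom_a = .data$chrom_a[1],
    chrom_b = .data$chrom_b[1],
    n_links = dplyr::n(),
    start_a = min(.data$start_a),
    end_a = max(.data$end_a),
    start_b = min(.data$start_b),
    end_b = max(.data$end_b),
    .groups = "drop"
  )
  blocks$links <- unname(lapply(
    split(links[setdiff(names(links), "block_id")], links$block_id),
    tibble::as_tibble
  ))
  blocks
}

#' Write links as a plain TSV
#'
#' @param links Link tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_links_tsv <- function(links, path) {
  validate_links(links)
  cols <- c("busco_id", "chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
  header <- paste(cols, collapse = "\t")
  body <- do.call(paste, c(lapply(cols, function(c) format_coord(links[[c]])), sep = "\t"))
  atomic_write_lines(c(header, body), path)
}

#' Read links from a plain TSV written by [write_links_tsv()]
#'
#' @param path Input path.
#' @return Link tibble.
#' @export
read_links_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric", "numeric",
                                          "character", "numeric", "numeric"))
  validate_links(tibble::as_tibble(tab))
}

format_coord <- function(x) {
  if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE) else x
}
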