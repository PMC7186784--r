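# Fixed 25-color cycle for genome-A chromosomes; black marks chromosomes
# outside the focal set.
CIRCOS_PALETTE <- c(
  "red", "orange", "yellow", "green", "blue", "purple", "dred", "dorange",
  "dyellow", "dgreen", "dblue", "dpurple", "lred", "lorange", "lyellow",
  "lgreen", "lblue", "lpurple", "vdred", "vdorange", "vdyellow", "vdgreen",
  "vdblue", "vdpurple", "grey"
)

#' Default chromosome color assignment
#'
#' Cycles a fixed 25-color list over the focal chromosomes, in order;
#' chromosomes not in the focal set get `"black"`.
#'
#' @param chrom_ids Chromosome ids to color.
#' @param focal Focal chromosome ids (default: all of `chrom_ids`).
#' @return Named character vector of Circos color tokens.
#' @export
circos_colors <- function(chrom_ids, focal = chrom_ids) {
  focal <- intersect(focal, chrom_ids)
  cols <- stats::setNames(rep("black", length(chrom_ids)), chrom_ids)
  if (length(focal)) {
    cols[focal] <- rep_len(CIRCOS_PALETTE, length(focal))
  }
  cols
}

#' Write a Circos karyotype file
#'
#' One line per chromosome in the standard dialect
#' `chr - ID LABEL START END COLOR` (space-separated, `START = 0`,
#' `END` = chromosome length in bases).
#'
#' @param chromosomes Tibble/data frame with columns `id`, `length`, and
#'   optionally `label` (default: id) and `color` (default: cycling palette).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_karyotype <- function(chromosomes, path) {
  if (!is.data.frame(chromosomes) || !all(c("id", "length") %in% names(chromosomes))) {
    abort("`chromosomes` must have columns id and length", class = "bsyn_parameter_error")
  }
  if (nrow(chromosomes) == 0L) {
    return(atomic_write_lines(character(), path))
  }
  if (anyDuplicated(chromosomes$id)) {
    abort("duplicate chromosome ids in karyotype", class = "bsyn_integrity_error")
  }
  if (any(chromosomes$length <= 0)) {
    abort("karyotype lengths must be positive", class = "bsyn_parameter_error")
  }
  label <- if ("label" %in% names(chromosomes)) chromosomes$label else chromosomes$id
  color <- if ("color" %in% names(chromosomes)) chromosomes$color else
    unname(circos_colors(chromosomes$id))
  lines <- paste("chr", "-", chromosomes$id, label, "0",
                 format_coord(chromosomes$length), color)
  atomic_write_lines(lines, path)
}

#' Read a Circos karyotype file written by [write_karyotype()]
#'
#' @param path Input path.
#' @return Tibble with columns `id`, `label`, `length`, `color`.
#' @export
read_karyotype <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(tibble::tibble(id = character(), label = character(),
                          length = numeric(), color = character()))
  }
  f <- stringi::stri_split_regex(lines, "\\s+")
  if (any(lengths(f) != 7L) || any(vapply(f, `[[`, character(1), 1) != "chr")) {
    abort("not a karyotype file in the 'chr - ID LABEL START END COLOR' dialect",
          class = "bsyn_parse_error")
  }
  tibble::tibble(
    id = vapply(f, `[[`, character(1), 3),
    label = vapply(f, `[[`, character(1), 4),
    length = as.numeric(vapply(f, `[[`, character(1), 6)),
    color = vapply(f, `[[`, character(1), 7)
  )
}

#' Write a Circos links file
#'
#' One line per synteny link in the modern two-segment dialect
#' `chrA startA endA chrB startB endB [color=...]` (space-separated), with a
#' deterministic ordering by (`chrom_a`, `start_a`, `busco_id`). Coordinates
#' are written 1-based as parsed; Circos tolerates this since karyotype
#' ranges start at 0 (stated in the file's header comment).
#'
#' @param links Link tibble from [build_links()] or
#'   [filter_single_relocations()].
#' @param path Output path.
#' @param color_by One of `"chrom_a"`, `"chrom_b"`, `"none"`: attach a
#'   `color=` parameter from the default palette keyed on that side's
#'   chromosome, or no color.
#' @param karyotype Optional karyotype tibble (as from [read_karyotype()] or
#'   with columns `id`, `length`): links referencing chromosomes absent from
#'   it, or with coordinates beyond the chromosome end, trigger a warning, or
#'   an error when `strict = TRUE`.
#' @param strict Escalate karyotype-consistency warnings to errors.
#' @return The path, invisibly.
#' @export
write_links_circos <- function(links, path, color_by = c("chrom_a", "chrom_b", "none"),
                               karyotype = NULL, strict = FALSE) {
  validate_links(links)
  color_by <- match.arg(color_by)
  links <- links[order(links$chrom_a, links$start_a, links$busco_id), ]

  if (!is.null(karyotype)) {
    check_links_against_karyotype(links, karyotype, strict)
  }

  colors <- switch(color_by,
    none = NULL,
    chrom_a = circos_colors(sort(unique(links$chrom_a)))[links$chrom_a],
    chrom_b = circos_colors(sort(unique(links$chrom_b)))[links$chrom_b]
  )
  body <- paste(
    links$chrom_a, format_coord(links$start_a), format_coord(links$end_a),
    links$chrom_b, format_coord(links$start_b), format_coord(links$end_b)
  )
  if (!is.null(colors)) body <- paste0(body, " color=", unname(colors))
  header <- "# coordinates are 1-based inclusive as parsed from BUSCO tables"
  atomic_write_lines(c(header, body), path)
}

check_links_against_karyotype <- function(links, karyotype, strict) {
  kmap <- stats::setNames(karyotype$length, karyotype$id)
  problems <- character()
  missing <- setdiff(unique(c(links$chrom_a, links$chrom_b)), names(kmap))
  if (length(missing)) {
    problems <- c(problems, paste0(
      "chromosome(s) absent from karyotype: ", paste(missing, collapse = ", ")
    ))
  }
  in_kar_a <- links$chrom_a %in% names(kmap)
  in_kar_b <- links$chrom_b %in% names(kmap)
  over <- (in_kar_a & links$end_a > kmap[links$chrom_a]) |
          (in_kar_b & links$end_b > kmap[links$chrom_b])
  if (any(over, na.rm = TRUE)) {
    problems <- c(problems, paste0(
      sum(over, na.rm = TRUE), " link(s) extend beyond their chromosome end"
    ))
  }
  if (length(problems)) {
    msg <- paste(problems, collapse = "; ")
    if (strict) abort(msg, class = "bsyn_coordinate_error") else warn(msg)
  }
  invisible(NULL)
}

#' Read a Circos links file written by [write_links_circos()]
#'
#' @param path Input path.
#' @return Tibble with columns `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `color` (NA when absent).
#' @export
read_links_circos <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(tibble::tibble(
      chrom_a = character(), start_a = numeric(), end_a = numeric(),
      chrom_b = character(), start_b = numeric(), end_b = numeric(),
      color = character()
    ))
  }
  f <- stringi::stri_split_regex(lines, "\\s+")
  if (any(!lengths(f) %in% c(6L, 7L))) {
    abort("not a two-segment Circos links file", class = "bsyn_parse_error")
  }
  col7 <- vapply(f, function(x) if (length(x) == 7L) x[[7]] else NA_character_,
                 character(1))
  tibble::tibble(
    chrom_a = vapply(f, `[[`, character(1), 1),
    start_a = as.numeric(vapply(f, `[[`, character(1), 2)),
    end_a = as.numeric(vapply(f, `[[`, character(1), 3)),
    chrom_b = vapply(f, `[[`, character(1), 4),
    start_b = as.numeric(vapply(f, `[[`, character(1), 5)),
    end_b = as.numeric(vapply(f, `[[`, character(1), 6)),
    color = sub("^color=", "", col7)
  )
}
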