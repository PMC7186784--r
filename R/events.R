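#' Build the chromosome-pair homology graph
#'
#' Collapses filtered synteny links into a bipartite graph: one vertex per
#' chromosome carrying links (on either genome), one edge per distinct
#' (`chrom_a`, `chrom_b`) pair, weighted by the number of supporting
#' single-copy orthologs. Connected components of this graph are the units on
#' which fusion/fission events are read off.
#'
#' @param links Link tibble, normally after [filter_single_relocations()].
#' @return A list with `edges` (tibble: `chrom_a`, `chrom_b`, `n_links`) and
#'   `graph` (an igraph bipartite graph; A-side vertices are named
#'   `"A:<chrom>"`, B-side `"B:<chrom>"`).
#' @export
build_graph <- function(links) {
  validate_links(links)
  edges <- dplyr::summarise(
    dplyr::group_by(links, .data$chrom_a, .data$chrom_b),
    n_links = dplyr::n(), .groups = "drop"
  )
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
  } else {
    el <- cbind(paste0("A:", edges$chrom_a), paste0("B:", edges$chrom_b))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::E(g)$n_links <- edges$n_links
    igraph::V(g)$type <- startsWith(igraph::V(g)$name, "B:")
  }
  list(edges = edges, graph = g)
}

#' Classify one connected homology component
#'
#' With `a` chromosomes of genome A and `b` of genome B in the component:
#' `a = b = 1` is `one_to_one` (0 events); `a = 1, b > 1` is `fusion_in_a`
#' (equivalently fission in B; `b - 1` events); `a > 1, b = 1` is
#' `fission_in_a` (`a - 1` events); `a > 1, b > 1` is `complex`, for which
#' `a + b - 2` is reported as the minimum number of fission + fusion events
#' able to explain the component -- a connected bipartite graph on `a + b`
#' vertices needs at least `a + b - 1` edges, and each event beyond a
#' one-to-one correspondence adds one.
#'
#' @param chroms_a,chroms_b Character vectors of the component's chromosomes
#'   on each side (each nonempty).
#' @return A list: `classification`, `n_events`, `n_chrom_a`, `n_chrom_b`.
#' @export
classify_component <- function(chroms_a, chroms_b) {
  a <- length(unique(chroms_a))
  b <- length(unique(chroms_b))
  if (a < 1L || b < 1L) {
    abort("a component must contain at least one chromosome on each side",
          class = "bsyn_parameter_error")
  }
  cls <- if (a == 1L && b == 1L) "one_to_one"
    else if (a == 1L) "fusion_in_a"
    else if (b == 1L) "fission_in_a"
    else "complex"
  list(
    classification = cls,
    n_events = a + b - 2L,
    n_chrom_a = a,
    n_chrom_b = b
  )
}

#' Fusion/fission event report between two genomes
#'
#' Runs the full event pipeline: filter single relocations, build the
#' chromosome-pair graph, split it into connected components, classify each
#' component, and aggregate. Event counts are *relative* between the two
#' genomes: a `fusion_in_a` component is equally a fission in B, and
#' assigning the event to a lineage requires an outgroup.
#'
#' @param links Link tibble from [build_links()] (unfiltered; filtering is
#'   applied here).
#' @param min_links Minimum supporting links per chromosome pair (default 2).
#' @param chroms_a,chroms_b Optional character vectors of all chromosomes of
#'   each genome; chromosomes with no surviving links are then listed as
#'   `unlinked_a` / `unlinked_b` rather than silently absent.
#' @return An object of class `event_report`: a list with `components`
#'   (tibble: `component`, `chroms_a`, `chroms_b`, `n_chrom_a`, `n_chrom_b`,
#'   `n_links`, `classification`, `n_events`), the aggregate counts
#'   `n_fusions_in_a`, `n_fissions_in_a`, `n_one_to_one`, `n_complex`,
#'   `n_events_total`, the filter settings, and `unlinked_a`/`unlinked_b`.
#' @export
event_report <- function(links, min_links = 2L, chroms_a = NULL, chroms_b = NULL) {
  validate_links(links)
  filtered <- filter_single_relocations(links, min_links = min_links)
  bg <- build_graph(filtered)
  comp_tbl <- component_table(bg)

  out <- list(
    components = comp_tbl,
    n_fusions_in_a = sum(comp_tbl$classification == "fusion_in_a"),
    n_fissions_in_a = sum(comp_tbl$classification == "fission_in_a"),
    n_one_to_one = sum(comp_tbl$classification == "one_to_one"),
    n_complex = sum(comp_tbl$classification == "complex"),
    n_events_total = sum(comp_tbl$n_events),
    min_links = as.integer(min_links),
    n_links_used = nrow(filtered),
    n_links_removed = attr(filtered, "n_removed"),
    unlinked_a = if (is.null(chroms_a)) character() else
      sort(setdiff(chroms_a, filtered$chrom_a)),
    unlinked_b = if (is.null(chroms_b)) character() else
      sort(setdiff(chroms_b, filtered$chrom_b)),
    orientation_note = paste(
      "Events are relative between the two genomes;",
      "lineage polarity requires an outgroup."
    )
  )
  class(out) <- "event_report"
  out
}

component_table <- function(bg) {
  empty <- tibble::tibble(
    component = integer(), chroms_a = character(), chroms_b = character(),
    n_chrom_a = integer(), n_chrom_b = integer(), n_links = integer(),
    classification = character(), n_events = integer()
  )
  if (nrow(bg$edges) == 0L) return(empty)
  memb <- igraph::components(bg$graph)$membership
  edge_comp <- memb[paste0("A:", bg$edges$chrom_a)]
  rows <- lapply(sort(unique(edge_comp)), function(k) {
    e <- bg$edges[edge_comp == k, ]
    ca <- sort(unique(e$chrom_a))
    cb <- sort(unique(e$chrom_b))
    cl <- classify_component(ca, cb)
    tibble::tibble(
      chroms_a = paste(ca, collapse = ","),
      chroms_b = paste(cb, collapse = ","),
      n_chrom_a = cl$n_chrom_a,
      n_chrom_b = cl$n_chrom_b,
      n_links = sum(e$n_links),
      classification = cl$classification,
      n_events = cl$n_events
    )
  })
  tbl <- dplyr::bind_rows(rows)
  tbl <- tbl[order(-tbl$n_links, tbl$chroms_a), ]
  tbl <- tibble::add_column(tbl, component = seq_len(nrow(tbl)), .before = 1)
  tbl
}

#' @exportS3Method base::format
format.event_report <- function(x, ...) {
  comp <- x$components
  lines <- c(
    sprintf("Homology components: %d (min_links = %d, %d link(s) used, %d removed as single relocations)",
            nrow(comp), x$min_links, x$n_links_used, x$n_links_removed),
    sprintf("  one-to-one: %d | fusions in A: %d | fissions in A: %d | complex: %d",
            x$n_one_to_one, x$n_fusions_in_a, x$n_fissions_in_a, x$n_complex),
    sprintf("  total events (minimum): %d", x$n_events_total),
    paste0("  note: ", x$orientation_note)
  )
  if (length(x$unlinked_a)) {
    lines <- c(lines, paste0("  unlinked in A: ", paste(x$unlinked_a, collapse = ", ")))
  }
  if (length(x$unlinked_b)) {
    lines <- c(lines, paste0("  unlinked in B: ", paste(x$unlinked_b, collapse = ", ")))
  }
  non11 <- comp[comp$classification != "one_to_one", ]
  if (nrow(non11)) {
    lines <- c(lines, "  non-trivial components:")
    lines <- c(lines, sprintf(
      "    [%d] {%s} ~ {%s}: %s, %d event(s), %d link(s)",
      non11$component, non11$chroms_a, non11$chroms_b,
      non11$classification, non11$n_events, non11$n_links
    ))
  }
  lines
}

#' @export
print.event_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write an event report's component table as TSV
#'
#' @param report An `event_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_event_tsv <- function(report, path) {
  comp <- report$components
  cols <- c("component", "chroms_a", "chroms_b", "n_chrom_a", "n_chrom_b",
            "n_links", "classification", "n_events")
  header <- paste(cols, collapse = "\t")
  body <- if (nrow(comp)) {
    do.call(paste, c(lapply(cols, function(c) format_coord(comp[[c]])), sep = "\t"))
  } else character()
  atomic_write_lines(c(header, body), path)
}
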