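#' Simulation configuration for a paired-genome karyotype experiment
#'
#' Defines the ancestral karyotype, the ortholog catalog placed on it, the
#' rearrangement events separating the two descendant genomes, the N-gap
#' scaffold structure, and the per-ortholog BUSCO status noise. The defaults
#' emulate a testudine-like contrast: a 27-chromosome ancestor, a catalog of
#' 3,950 orthologs (the size of a typical tetrapod BUSCO set), two fusion
#' events in the derived genome, and low duplication/fragmentation/missing
#' rates of the order observed in high-quality chelonian assemblies.
#' Chromosome lengths are scaled down to the sub-megabase range so that
#' paired genomes remain cheap to generate; ortholog density per chromosome,
#' which is what the synteny method consumes, is preserved.
#'
#' @param n_ancestral_chroms Number of ancestral chromosomes.
#' @param chrom_length_range Ancestral chromosome length range in bases.
#' @param n_orthologs Size of the ortholog catalog.
#' @param ortholog_length_range Length range of an ortholog interval.
#' @param events Ordered list of events built with [sim_event()], applied to
#'   genome B in order.
#' @param n_gap_runs_per_chrom N-gap runs overwritten into each ancestral
#'   chromosome.
#' @param gap_length_range Gap run length range in bases.
#' @param missing_rate,duplicate_rate,fragment_rate Per-ortholog,
#'   per-genome probabilities of BUSCO status noise.
#' @param seed Integer seed; all randomness in [simulate_pair()] flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ancestral_chroms = 27L,
                       chrom_length_range = c(2e5, 8e5),
                       n_orthologs = 3950L,
                       ortholog_length_range = c(200, 2000),
                       events = list(sim_event("fusion"), sim_event("fusion")),
                       n_gap_runs_per_chrom = 5L,
                       gap_length_range = c(10, 8000),
                       missing_rate = 0.015,
                       duplicate_rate = 0.006,
                       fragment_rate = 0.027,
                       seed = 1L) {
  cfg <- list(
    n_ancestral_chroms = stopifnot_scalar_count(n_ancestral_chroms, "n_ancestral_chroms"),
    chrom_length_range = as.numeric(chrom_length_range),
    n_orthologs = stopifnot_scalar_count(n_orthologs, "n_orthologs"),
    ortholog_length_range = as.numeric(ortholog_length_range),
    events = events,
    n_gap_runs_per_chrom = stopifnot_scalar_count(n_gap_runs_per_chrom,
                                                  "n_gap_runs_per_chrom", min = 0L),
    gap_length_range = as.numeric(gap_length_range),
    missing_rate = missing_rate,
    duplicate_rate = duplicate_rate,
    fragment_rate = fragment_rate,
    seed = stopifnot_scalar_count(seed, "seed", min = 0L)
  )
  for (r in c("missing_rate", "duplicate_rate", "fragment_rate")) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1) {
      abort(paste0("`", r, "` must lie in [0, 1]"), class = "bsyn_config_error")
    }
  }
  for (rng in c("chrom_length_range", "ortholog_length_range", "gap_length_range")) {
    v <- cfg[[rng]]
    if (length(v) != 2L || any(v < 1) || v[1] > v[2]) {
      abort(paste0("`", rng, "` must be [min, max] with 1 <= min <= max"),
            class = "bsyn_config_error")
    }
  }
  if (cfg$n_orthologs < 2L * cfg$n_ancestral_chroms) {
    abort("`n_orthologs` must be at least 2 per ancestral chromosome",
          class = "bsyn_config_error")
  }
  if (!is.list(cfg$events) ||
      !all(vapply(cfg$events, function(e) inherits(e, "sim_event"), logical(1)))) {
    abort("`events` must be a list of sim_event() objects", class = "bsyn_config_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Declare one rearrangement event
#'
#' @param type `"fusion"` (concatenate two chromosomes with a 100-N junction
#'   gap), `"fission"` (split one chromosome at a breakpoint outside any
#'   ortholog), or `"relocation"` (move a single ortholog to another
#'   chromosome).
#' @param chroms Chromosome name(s) the event acts on (two for fusion, one
#'   for fission, target for relocation); `NULL` draws them at simulation
#'   time.
#' @param ortholog For relocation: the ortholog id to move (`NULL` draws one).
#' @param breakpoint For fission: the breakpoint (`NULL` draws one uniformly).
#' @return A `sim_event` object.
#' @export
sim_event <- function(type = c("fusion", "fission", "relocation"),
                      chroms = NULL, ortholog = NULL, breakpoint = NULL) {
  type <- match.arg(type)
  structure(
    list(type = type, chroms = chroms, ortholog = ortholog, breakpoint = breakpoint),
    class = "sim_event"
  )
}

FUSION_GAP <- 100L

#' Simulate a pair of genomes with a known rearrangement history
#'
#' Draws an ancestral karyotype, places the ortholog catalog uniformly along
#' it with non-overlapping intervals, overwrites N-gap runs into the
#' chromosomes, then derives genome B from the ancestor (genome A) by
#' applying the configured events in order. BUSCO-style tables for both
#' genomes are produced from the true placements with independent
#' per-ortholog status noise. Everything is reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param sequences Generate the FASTA sequences (default `TRUE`). With
#'   `FALSE` the returned `fasta_a`/`fasta_b` are `NULL`; placements, tables
#'   and truth are unchanged for a given seed.
#' @return A list with `fasta_a`, `fasta_b` (record tibbles as from
#'   [read_fasta()]), `busco_a`, `busco_b` (BUSCO record tibbles), and
#'   `truth` (chromosome maps of both genomes, true noise-free placements,
#'   and the realized event list).
#' @export
simulate_pair <- function(config, sequences = TRUE) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must come from sim_config()", class = "bsyn_config_error")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_ancestral_chroms
  anc <- tibble::tibble(
    chrom = paste0("chr", seq_len(n)),
    length = floor(stats::runif(n, config$chrom_length_range[1],
                                config$chrom_length_range[2] + 1))
  )

  placements <- place_orthologs(anc, config)
  gaps <- place_gap_runs(anc, placements, config)

  b <- apply_events(anc, placements, config$events)

  busco_a <- busco_noise(placements, anc, config)
  busco_b <- busco_noise(b$placements, b$chroms, config)

  fasta_a <- fasta_b <- NULL
  if (sequences) {
    seq_a <- stats::setNames(
      stringi::stri_rand_strings(n, anc$length, "[ACGT]"), anc$chrom
    )
    for (i in seq_len(nrow(gaps))) {
      stringi::stri_sub(seq_a[gaps$chrom[i]], gaps$start[i], gaps$end[i]) <-
        strrep("N", gaps$end[i] - gaps$start[i] + 1L)
    }
    fasta_a <- tibble::tibble(id = anc$chrom, description = "", seq = unname(seq_a))
    fasta_b <- build_b_sequences(seq_a, b$chroms)
  }

  list(
    fasta_a = fasta_a,
    fasta_b = fasta_b,
    busco_a = busco_a,
    busco_b = busco_b,
    truth = list(
      ancestor = anc,
      chroms_a = anc,
      chroms_b = b$chroms[c("chrom", "length")],
      segments_b = b$chroms$segments,
      placements_a = placements,
      placements_b = b$placements,
      gaps_a = gaps,
      events = b$events,
      config = config
    )
  )
}

# Uniform non-overlapping interval placement: orthologs are assigned to
# chromosomes with probability proportional to length, then laid out on each
# chromosome by distributing the free slack uniformly between them.
place_orthologs <- function(anc, config) {
  ids <- sprintf("BUSCO%05d", seq_len(config$n_orthologs))
  chrom_of <- sample(anc$chrom, config$n_orthologs, replace = TRUE,
                     prob = anc$length)
  lens <- floor(stats::runif(config$n_orthologs,
                             config$ortholog_length_range[1],
                             config$ortholog_length_range[2] + 1))
  out <- vector("list", nrow(anc))
  for (i in seq_len(nrow(anc))) {
    on_chrom <- which(chrom_of == anc$chrom[i])
    if (!length(on_chrom)) next
    k <- length(on_chrom)
    l <- lens[on_chrom]
    slack <- anc$length[i] - sum(l)
    if (slack < k) {
      abort(paste0("orthologs do not fit on ", anc$chrom[i],
                   "; increase chromosome lengths or reduce the catalog"),
            class = "bsyn_config_error")
    }
    offsets <- sort(floor(stats::runif(k, 0, slack)))
    starts <- offsets + c(0, cumsum(l[-k])) + 1
    out[[i]] <- tibble::tibble(
      busco_id = ids[on_chrom],
      chrom = anc$chrom[i],
      start = starts,
      end = starts + l - 1,
      strand = sample(c("+", "-"), k, replace = TRUE)
    )
  }
  dplyr::bind_rows(out)
}

# Overwrite N-runs into regions free of orthologs and other gaps.
place_gap_runs <- function(anc, placements, config) {
  if (config$n_gap_runs_per_chrom == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  rows <- list()
  for (i in seq_len(nrow(anc))) {
    occupied <- placements[placements$chrom == anc$chrom[i], c("start", "end")]
    placed <- 0L
    tries <- 0L
    while (placed < config$n_gap_runs_per_chrom && tries < 100L * config$n_gap_runs_per_chrom) {
      tries <- tries + 1L
      glen <- floor(stats::runif(1, config$gap_length_range[1],
                                 config$gap_length_range[2] + 1))
      if (glen >= anc$length[i]) next
      gstart <- floor(stats::runif(1, 1, anc$length[i] - glen + 1))
      gend <- gstart + glen - 1
      if (nrow(occupied) && any(gstart <= occupied$end & gend >= occupied$start)) next
      occupied <- rbind(occupied, data.frame(start = gstart, end = gend))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(chrom = anc$chrom[i], start = gstart, end = gend)
      placed <- placed + 1L
    }
  }
  dplyr::bind_rows(rows)
}

# Apply the event list to derive genome B. Chromosomes are tracked as
# segment lists over the ancestor so that sequences and truth maps can be
# replayed exactly.
apply_events <- function(anc, placements, events) {
  chroms <- tibble::tibble(
    chrom = anc$chrom, length = anc$length,
    segments = lapply(seq_len(nrow(anc)), function(i) {
      tibble::tibble(src = anc$chrom[i], src_start = 1,
                     src_end = anc$length[i], gap = 0)
    })
  )
  pl <- placements
  realized <- list()

  pick <- function(pool, k, requested, what) {
    if (is.null(requested)) {
      if (length(pool) < k) {
        abort(paste0("not enough chromosomes left for a ", what),
              class = "bsyn_config_error")
      }
      return(sample(pool, k))
    }
    if (!all(requested %in% pool)) {
      abort(paste0(what, " references nonexistent chromosome(s): ",
                   paste(setdiff(requested, pool), collapse = ", ")),
            class = "bsyn_config_error")
    }
    requested
  }

  for (ev in events) {
    if (ev$type == "fusion") {
      cs <- pick(chroms$chrom, 2L, ev$chroms, "fusion")
      i1 <- match(cs[1], chroms$chrom); i2 <- match(cs[2], chroms$chrom)
      new_name <- paste0(cs[1], "+", cs[2])
      shift <- chroms$length[i1] + FUSION_GAP
      seg <- dplyr::bind_rows(
        chroms$segments[[i1]],
        tibble::tibble(src = NA_character_, src_start = NA_real_,
                       src_end = NA_real_, gap = FUSION_GAP),
        chroms$segments[[i2]]
      )
      new_len <- chroms$length[i1] + FUSION_GAP + chroms$length[i2]
      pl$start[pl$chrom == cs[2]] <- pl$start[pl$chrom == cs[2]] + shift
      pl$end[pl$chrom == cs[2]] <- pl$end[pl$chrom == cs[2]] + shift
      pl$chrom[pl$chrom %in% cs] <- new_name
      chroms$chrom[i1] <- new_name
      chroms$length[i1] <- new_len
      chroms$segments[[i1]] <- seg
      chroms <- chroms[-i2, ]
      realized[[length(realized) + 1L]] <-
        list(type = "fusion", chroms = cs, result = new_name)
    } else if (ev$type == "fission") {
      cs <- pick(chroms$chrom, 1L, ev$chroms, "fission")
      i <- match(cs, chroms$chrom)
      L <- chroms$length[i]
      on_c <- pl[pl$chrom == cs, ]
      bp <- ev$breakpoint
      if (is.null(bp)) {
        ok <- FALSE
        for (try in seq_len(100L)) {
          bp <- floor(stats::runif(1, 1, L))
          if (!nrow(on_c) || !any(on_c$start <= bp & bp < on_c$end)) { ok <- TRUE; break }
        }
        if (!ok) {
          abort(paste0("no ortholog-free breakpoint found on ", cs,
                       " after 100 tries"), class = "bsyn_config_error")
        }
      } else if (nrow(on_c) && any(on_c$start <= bp & bp < on_c$end)) {
        abort("requested fission breakpoint falls inside an ortholog",
              class = "bsyn_config_error")
      }
      parts <- split_segments(chroms$segments[[i]], bp)
      n1 <- paste0(cs, ".1"); n2 <- paste0(cs, ".2")
      left <- pl$chrom == cs & pl$end <= bp
      right <- pl$chrom == cs & pl$start > bp
      pl$chrom[left] <- n1
      pl$chrom[right] <- n2
      pl$start[right] <- pl$start[right] - bp
      pl$end[right] <- pl$end[right] - bp
      chroms <- dplyr::bind_rows(
        chroms[seq_len(i - 1L), ],
        tibble::tibble(chrom = n1, length = bp, segments = list(parts$left)),
        tibble::tibble(chrom = n2, length = L - bp, segments = list(parts$right)),
        chroms[-seq_len(i), ]
      )
      realized[[length(realized) + 1L]] <-
        list(type = "fission", chroms = cs, breakpoint = bp, result = c(n1, n2))
    } else { # relocation
      o_id <- ev$ortholog
      if (is.null(o_id)) o_id <- sample(pl$busco_id, 1L)
      if (!o_id %in% pl$busco_id) {
        abort(paste0("relocation references unknown ortholog ", o_id),
              class = "bsyn_config_error")
      }
      oi <- match(o_id, pl$busco_id)
      olen <- pl$end[oi] - pl$start[oi] + 1
      target_pool <- setdiff(chroms$chrom, pl$chrom[oi])
      target <- pick(target_pool, 1L, ev$chroms, "relocation")
      ti <- match(target, chroms$chrom)
      others <- pl[pl$chrom == target, c("start", "end")]
      ok <- FALSE
      for (try in seq_len(100L)) {
        s <- floor(stats::runif(1, 1, chroms$length[ti] - olen + 1))
        e <- s + olen - 1
        if (!nrow(others) || !any(s <= others$end & e >= others$start)) { ok <- TRUE; break }
      }
      if (!ok) {
        abort(paste0("no free position for relocation onto ", target,
                     " after 100 tries"), class = "bsyn_config_error")
      }
      pl$chrom[oi] <- target
      pl$start[oi] <- s
      pl$end[oi] <- e
      realized[[length(realized) + 1L]] <-
        list(type = "relocation", ortholog = o_id, target = target,
             position = c(s, e))
    }
  }
  list(chroms = chroms, placements = pl, events = realized)
}

# Split a segment list at offset bp (left part covers 1..bp).
split_segments <- function(segments, bp) {
  lens <- ifelse(segments$gap > 0, segments$gap,
                 segments$src_end - segments$src_start + 1)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  k <- which(bp >= starts & bp <= ends)[1]
  left <- segments[seq_len(k), ]
  right <- segments[seq(k, nrow(segments)), ]
  within <- bp - starts[k] + 1
  if (left$gap[k] > 0) {
    left$gap[k] <- within
    right$gap[1] <- lens[k] - within
    if (right$gap[1] == 0) right <- right[-1, , drop = FALSE]
  } else {
    left$src_end[k] <- left$src_start[k] + within - 1
    right$src_start[1] <- right$src_start[1] + within
    if (right$src_start[1] > right$src_end[1]) right <- right[-1, , drop = FALSE]
  }
  list(left = left, right = right)
}

build_b_sequences <- function(seq_a, chroms_b) {
  seqs <- vapply(seq_len(nrow(chroms_b)), function(i) {
    seg <- chroms_b$segments[[i]]
    pieces <- vapply(seq_len(nrow(seg)), function(j) {
      if (seg$gap[j] > 0) strrep("N", seg$gap[j])
      else stringi::stri_sub(seq_a[seg$src[j]], seg$src_start[j], seg$src_end[j])
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  tibble::tibble(id = chroms_b$chrom, description = "", seq = seqs)
}

# Turn true placements into a noisy BUSCO record table for one genome.
busco_noise <- function(placements, chroms, config) {
  u <- stats::runif(nrow(placements))
  p_m <- config$missing_rate
  p_d <- p_m + config$duplicate_rate
  p_f <- p_d + config$fragment_rate
  status <- ifelse(u < p_m, "Missing",
            ifelse(u < p_d, "Duplicated",
            ifelse(u < p_f, "Fragmented", "Complete")))
  placed <- status != "Missing"
  tbl <- tibble::tibble(
    busco_id = placements$busco_id,
    status = status,
    scaffold_id = ifelse(placed, placements$chrom, NA_character_),
    start = ifelse(placed, placements$start, NA_real_),
    end = ifelse(placed, placements$end, NA_real_),
    strand = ifelse(placed, placements$strand, NA_character_),
    score = ifelse(placed, round(stats::runif(nrow(placements), 100, 2000), 1), NA_real_),
    length = ifelse(placed, placements$end - placements$start + 1, NA_real_),
    source_direction = "forward"
  )
  dup <- which(status == "Duplicated")
  if (length(dup)) {
    extra <- tbl[dup, ]
    ti <- sample.int(nrow(chroms), length(dup), replace = TRUE)
    olen <- extra$end - extra$start + 1
    extra$scaffold_id <- chroms$chrom[ti]
    extra$start <- floor(stats::runif(length(dup), 1,
                                      pmax(2, chroms$length[ti] - olen + 1)))
    extra$end <- extra$start + olen - 1
    tbl <- dplyr::bind_rows(tbl, extra)
  }
  tbl <- tbl[order(tbl$busco_id, tbl$start), ]
  tbl
}

#' Write BUSCO records as a full-table file
#'
#' @param records BUSCO record tibble.
#' @param path Output path.
#' @param dialect `"v5"` (with a `Strand` column) or `"v2"` (the seven-column
#'   layout without strand). `parse_full_table()` reads both back.
#' @return The path, invisibly.
#' @export
write_busco_table <- function(records, path, dialect = c("v5", "v2")) {
  dialect <- match.arg(dialect)
  validate_busco_tbl(records)
  fmt_na <- function(x) ifelse(is.na(x), "N/A", format_coord(x))
  placed <- records$status != "Missing"
  lines <- character(nrow(records))
  if (dialect == "v5") {
    header <- c("# BUSCO full table",
                "# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength")
    strand <- ifelse(is.na(records$strand), "+", records$strand)
    lines[placed] <- paste(
      records$busco_id[placed], records$status[placed], records$scaffold_id[placed],
      format_coord(records$start[placed]), format_coord(records$end[placed]),
      strand[placed], fmt_na(records$score[placed]), fmt_na(records$length[placed]),
      sep = "\t"
    )
  } else {
    header <- c("# BUSCO full table",
                "# Busco id\tStatus\tContig\tStart\tEnd\tScore\tLength")
    lines[placed] <- paste(
      records$busco_id[placed], records$status[placed], records$scaffold_id[placed],
      format_coord(records$start[placed]), format_coord(records$end[placed]),
      fmt_na(records$score[placed]), fmt_na(records$length[placed]),
      sep = "\t"
    )
  }
  lines[!placed] <- paste(records$busco_id[!placed], "Missing", sep = "\t")
  atomic_write_lines(c(header, lines), path)
}

#' Write a simulated pair to a directory
#'
#' Emits `genomeA.fa`, `genomeB.fa`, `busco_A.tsv`, `busco_B.tsv` (v5
#' dialect) and `truth.json`.
#'
#' @param sim Result of [simulate_pair()] (with sequences).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dir <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(sim$fasta_a)) {
    abort("simulation was run without sequences; rerun with sequences = TRUE",
          class = "bsyn_parameter_error")
  }
  write_fasta(sim$fasta_a, file.path(dir, "genomeA.fa"))
  write_fasta(sim$fasta_b, file.path(dir, "genomeB.fa"))
  write_busco_table(sim$busco_a, file.path(dir, "busco_A.tsv"))
  write_busco_table(sim$busco_b, file.path(dir, "busco_B.tsv"))
  truth <- sim$truth
  truth$segments_b <- NULL
  truth$config$events <- lapply(truth$config$events, unclass)
  atomic_write_lines(
    jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     na = "null", force = TRUE),
    file.path(dir, "truth.json")
  )
  invisible(dir)
}
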