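# In-code fixtures and independent oracles shared across test files.

make_records <- function(seqs, ids = paste0("s", seq_along(seqs)), desc = "") {
  tibble::tibble(id = ids, description = desc, seq = seqs)
}

# Random DNA with optional embedded N-runs at random positions.
random_scaffold <- function(len, n_runs = 0, run_len_range = c(1, 30)) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  for (i in seq_len(n_runs)) {
    rl <- sample(run_len_range[1]:run_len_range[2], 1)
    if (rl >= len) next
    at <- sample.int(len - rl + 1, 1)
    substr(s, at, at + rl - 1) <- strrep("N", rl)
  }
  s
}

# One-row BUSCO record constructor.
busco_row <- function(id, status, scaffold = NA, start = NA, end = NA,
                      strand = NA, score = NA, len = NA, src = "forward") {
  tibble::tibble(
    busco_id = id, status = status,
    scaffold_id = as.character(scaffold),
    start = as.numeric(start), end = as.numeric(end),
    strand = as.character(strand), score = as.numeric(score),
    length = as.numeric(len), source_direction = src
  )
}

sco_tbl <- function(ids, chrom, start, end) {
  tibble::tibble(
    busco_id = ids, chromosome_id = chrom,
    start = as.numeric(start), end = as.numeric(end),
    source_direction = "forward"
  )
}

make_links <- function(chrom_a, chrom_b, start_a = seq_along(chrom_a) * 100,
                       ids = sprintf("B%03d", seq_along(chrom_a))) {
  tibble::tibble(
    busco_id = ids,
    chrom_a = chrom_a, start_a = as.numeric(start_a), end_a = as.numeric(start_a) + 10,
    chrom_b = chrom_b, start_b = as.numeric(start_a) + 5, end_b = as.numeric(start_a) + 15
  )
}

# Independent Nx/Lx oracle: walk the descending-sorted lengths one by one.
nx_oracle <- function(lengths, x) {
  sorted <- sort(lengths, decreasing = TRUE)
  target <- ceiling(x / 100 * sum(as.numeric(sorted)))
  acc <- 0
  for (i in seq_along(sorted)) {
    acc <- acc + sorted[i]
    if (acc >= target) return(list(n = sorted[i], l = i))
  }
}

# Independent contig oracle: walk the sequence character by character to
# find the maximal N-runs, call those of >= min_gap gaps, and emit the
# nonempty complement intervals as contigs. Linear scan, no regex.
contig_oracle <- function(seq, min_gap = 10) {
  chars <- strsplit(seq, "")[[1]]
  is_n <- chars %in% c("N", "n")
  L <- length(chars)
  gaps <- list()
  i <- 1
  while (i <= L) {
    if (is_n[i]) {
      j <- i
      while (j < L && is_n[j + 1]) j <- j + 1
      if (j - i + 1 >= min_gap) gaps[[length(gaps) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  bounds <- c(0, unlist(gaps), L + 1)
  starts <- bounds[seq(1, length(bounds), by = 2)] + 1
  ends <- bounds[seq(2, length(bounds), by = 2)] - 1
  keep <- starts <= ends
  if (!any(keep)) return(NULL)
  cbind(starts[keep], ends[keep])
}

# Minimum fusion+fission oracle: BFS over multisets of block-sets, starting
# from the A-side grouping of a component's edges and ending at the B-side
# grouping. Fusion = union of two sets; fission = any bipartition of a set.
min_events_oracle <- function(from_sets, to_sets) {
  canon <- function(sets) {
    paste(sort(vapply(sets, function(s) paste(sort(s), collapse = ","), "")),
          collapse = "|")
  }
  target <- canon(to_sets)
  frontier <- list(from_sets)
  seen <- canon(from_sets)
  depth <- 0
  while (TRUE) {
    if (target %in% seen) return(depth)
    nxt <- list()
    for (state in frontier) {
      n <- length(state)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i < j) { # fusion
            cand <- c(state[-c(i, j)], list(union(state[[i]], state[[j]])))
            if (!canon(cand) %in% seen) {
              nxt <- c(nxt, list(cand)); seen <- c(seen, canon(cand))
            }
          }
        }
        blk <- state[[i]]
        if (length(blk) > 1) { # fission: all bipartitions
          for (mask in 1:(2^length(blk) - 2)) {
            sel <- as.logical(bitwAnd(mask, 2^(seq_along(blk) - 1)))
            cand <- c(state[-i], list(blk[sel]), list(blk[!sel]))
            if (!canon(cand) %in% seen) {
              nxt <- c(nxt, list(cand)); seen <- c(seen, canon(cand))
            }
          }
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1
    if (depth > 8) stop("oracle depth exceeded")
  }
}

# Small fast simulator config for pipeline tests.
test_sim_config <- function(events, seed, n_chroms = 6L, n_orth = 150L,
                            noise = 0, sequences_len = c(4e4, 8e4)) {
  sim_config(
    n_ancestral_chroms = n_chroms,
    chrom_length_range = sequences_len,
    n_orthologs = n_orth,
    ortholog_length_range = c(100, 400),
    events = events,
    n_gap_runs_per_chrom = 2L,
    gap_length_range = c(10, 300),
    missing_rate = noise, duplicate_rate = noise, fragment_rate = noise,
    seed = seed
  )
}
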