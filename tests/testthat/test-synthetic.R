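test_that("identical configs give byte-identical outputs", {
  cfg <- test_sim_config(list(sim_event("fusion")), seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim_dir(simulate_pair(cfg), d1)
  write_sim_dir(simulate_pair(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the draw
  other <- simulate_pair(test_sim_config(list(sim_event("fusion")), seed = 8))
  expect_false(identical(other$truth$placements_a,
                         simulate_pair(cfg)$truth$placements_a))
})

test_that("the null model yields identical genomes and zero events", {
  sim <- simulate_pair(test_sim_config(list(), seed = 3))
  expect_equal(sim$fasta_a$seq, sim$fasta_b$seq)
  expect_equal(sim$truth$chroms_a$length, sim$truth$chroms_b$length)
  expect_equal(busco_summary(sim$busco_a)$n_missing, 0)
  rep <- event_report(build_links(extract_sco_set(sim$busco_a),
                                  extract_sco_set(sim$busco_b)))
  expect_true(all(rep$components$classification == "one_to_one"))
  expect_equal(rep$n_events_total, 0)
})

test_that("two planted fusions with zero noise are recovered exactly", {
  cfg <- test_sim_config(list(sim_event("fusion"), sim_event("fusion")),
                         seed = 7, n_chroms = 5L, n_orth = 100L)
  sim <- simulate_pair(cfg, sequences = FALSE)
  links <- build_links(extract_sco_set(sim$busco_b), extract_sco_set(sim$busco_a))
  rep <- event_report(links)
  fus <- rep$components[rep$components$classification == "fusion_in_a", ]
  expect_equal(sum(fus$n_events), 2)
  expect_equal(rep$n_fissions_in_a, 0)
  expect_equal(length(sim$truth$events), 2)
})

test_that("fusion junctions couple the synteny and assembly-stats surfaces", {
  cfg <- test_sim_config(list(sim_event("fusion", chroms = c("chr1", "chr2"))),
                         seed = 13, n_chroms = 4L, n_orth = 40L)
  cfg$n_gap_runs_per_chrom <- 0L
  sim <- simulate_pair(cfg)
  fused <- sim$fasta_b[sim$fasta_b$id == "chr1+chr2", ]
  expect_equal(nrow(fused), 1)
  parts <- split_into_contigs(fused)
  expect_equal(nrow(parts$contigs), 2)
  expect_equal(parts$gaps, 100L)
  lens_a <- scaffold_lengths(sim$fasta_a)
  expect_equal(nchar(fused$seq), unname(lens_a["chr1"] + lens_a["chr2"] + 100))
  # junction sequence is the two ancestors joined by the 100-N gap
  expect_identical(
    fused$seq,
    paste0(sim$fasta_a$seq[sim$fasta_a$id == "chr1"], strrep("N", 100),
           sim$fasta_a$seq[sim$fasta_a$id == "chr2"])
  )
})

test_that("fission and relocation truth maps replay exactly", {
  cfg <- test_sim_config(list(sim_event("fission", chroms = "chr2"),
                              sim_event("relocation")),
                         seed = 17, n_chroms = 4L, n_orth = 60L)
  sim <- simulate_pair(cfg)
  tb <- sim$truth$chroms_b
  expect_setequal(c("chr2.1", "chr2.2"), tb$chrom[grepl("^chr2", tb$chrom)])
  lens_a <- scaffold_lengths(sim$fasta_a)
  expect_equal(sum(tb$length[grepl("^chr2", tb$chrom)]), unname(lens_a["chr2"]))
  expect_equal(scaffold_lengths(sim$fasta_b), stats::setNames(tb$length, tb$chrom))
  # the fission halves are literal substrings of the ancestral chromosome
  anc <- sim$fasta_a$seq[sim$fasta_a$id == "chr2"]
  bp <- sim$truth$events[[1]]$breakpoint
  expect_identical(sim$fasta_b$seq[sim$fasta_b$id == "chr2.1"],
                   substr(anc, 1, bp))
  expect_identical(sim$fasta_b$seq[sim$fasta_b$id == "chr2.2"],
                   substr(anc, bp + 1, nchar(anc)))
})

test_that("every ortholog Complete in both noisy tables becomes a link", {
  cfg <- test_sim_config(list(sim_event("fusion")), seed = 23, noise = 0.05)
  sim <- simulate_pair(cfg, sequences = FALSE)
  sa <- extract_sco_set(sim$busco_a)
  sb <- extract_sco_set(sim$busco_b)
  links <- build_links(sa, sb)
  expect_setequal(links$busco_id, intersect(sa$busco_id, sb$busco_id))
  expect_true(busco_summary(sim$busco_a)$n_missing > 0)
})

test_that("BUSCO tables round-trip through both dialects", {
  cfg <- test_sim_config(list(), seed = 29, n_chroms = 4L, n_orth = 50L,
                         noise = 0.08)
  sim <- simulate_pair(cfg, sequences = FALSE)
  tbl <- sim$busco_a
  v5 <- withr::local_tempfile(fileext = ".tsv")
  v2 <- withr::local_tempfile(fileext = ".tsv")
  write_busco_table(tbl, v5, dialect = "v5")
  write_busco_table(tbl, v2, dialect = "v2")
  b5 <- parse_full_table(v5)
  b2 <- parse_full_table(v2)
  shared <- c("busco_id", "status", "scaffold_id", "start", "end", "score", "length")
  expect_equal(b5[shared], tbl[shared], ignore_attr = TRUE)
  expect_equal(b2[shared], tbl[shared], ignore_attr = TRUE)
  expect_equal(b5$strand, tbl$strand)
  expect_true(all(is.na(b2$strand)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(missing_rate = 1.5), class = "bsyn_config_error")
  expect_error(sim_config(chrom_length_range = c(10, 5)), class = "bsyn_config_error")
  expect_error(sim_config(n_orthologs = 10, n_ancestral_chroms = 6),
               class = "bsyn_config_error")
  expect_error(
    simulate_pair(test_sim_config(list(sim_event("fusion", chroms = c("chr1", "nope"))),
                                  seed = 1)),
    class = "bsyn_config_error"
  )
})
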