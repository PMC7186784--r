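test_that("the homology graph groups links into weighted chromosome-pair edges", {
  links <- make_links(
    chrom_a = c("c1", "c1", "c1", "c1", "c1"),
    chrom_b = c("d1", "d1", "d1", "d2", "d2")
  )
  bg <- build_graph(links)
  expect_equal(nrow(bg$edges), 2)
  expect_setequal(bg$edges$n_links, c(3, 2))
  expect_equal(sum(bg$edges$n_links), nrow(links))

  empty <- build_graph(links[0, ])
  expect_equal(nrow(empty$edges), 0)
})

test_that("component classification follows chromosome counts on each side", {
  one <- classify_component("c1", "d1")
  expect_equal(one$classification, "one_to_one")
  expect_equal(one$n_events, 0)

  fus <- classify_component("c1", c("d1", "d2", "d3"))
  expect_equal(fus$classification, "fusion_in_a")
  expect_equal(fus$n_events, 2)

  fis <- classify_component(c("c1", "c2"), "d1")
  expect_equal(fis$classification, "fission_in_a")
  expect_equal(fis$n_events, 1)

  cx <- classify_component(c("c1", "c2"), c("d1", "d2"))
  expect_equal(cx$classification, "complex")
  expect_equal(cx$n_events, 2)

  expect_error(classify_component(character(), "d1"), class = "bsyn_parameter_error")
})

test_that("a + b - 2 is the minimum event count over small bipartite topologies", {
  # Enumerate every connected bipartite topology with up to 3 chromosomes a
  # side; each edge is one SCO block. The oracle searches fusion/fission
  # sequences turning the A-side grouping of blocks into the B-side grouping.
  for (a in 1:3) {
    for (b in 1:3) {
      if (a * b > 6) next
      edges <- expand.grid(i = seq_len(a), j = seq_len(b))
      n_edges <- nrow(edges)
      for (mask in 1:(2^n_edges - 1)) {
        sel <- edges[as.logical(bitwAnd(mask, 2^(seq_len(n_edges) - 1))), ]
        if (length(unique(sel$i)) < a || length(unique(sel$j)) < b) next
        g <- igraph::graph_from_edgelist(
          cbind(paste0("A", sel$i), paste0("B", sel$j)), directed = FALSE)
        if (igraph::components(g)$no != 1) next
        blocks <- seq_len(nrow(sel))
        from <- lapply(seq_len(a), function(i) blocks[sel$i == i])
        to <- lapply(seq_len(b), function(j) blocks[sel$j == j])
        expect_equal(min_events_oracle(from, to), a + b - 2,
                     info = paste("a =", a, "b =", b, "mask =", mask))
      }
    }
  }
})

test_that("identical genomes yield only one-to-one components and zero events", {
  sco <- sco_tbl(sprintf("B%02d", 1:30), rep(paste0("c", 1:5), each = 6),
                 rep(1:6 * 100, 5), rep(1:6 * 100 + 50, 5))
  rep <- event_report(build_links(sco, sco))
  expect_equal(nrow(rep$components), 5)
  expect_true(all(rep$components$classification == "one_to_one"))
  expect_equal(rep$n_events_total, 0)
})

test_that("planted fusions are recovered as fusion events of the derived genome", {
  for (k in 0:3) {
    events <- replicate(k, sim_event("fusion"), simplify = FALSE)
    sim <- simulate_pair(test_sim_config(events, seed = 100 + k), sequences = FALSE)
    # genome B carries the fusions; with B as the A-side of the links the
    # planted fusions surface as fusion_in_a components. A fusion drawing an
    # already-fused chromosome chains: one component then carries two events,
    # so events (not components) are the recovered quantity.
    links <- build_links(extract_sco_set(sim$busco_b), extract_sco_set(sim$busco_a))
    rep <- event_report(links)
    fus <- rep$components[rep$components$classification == "fusion_in_a", ]
    expect_equal(sum(fus$n_events), k, info = paste("k =", k))
    expect_equal(rep$n_fissions_in_a, 0)
    expect_equal(rep$n_complex, 0)
    expect_equal(rep$n_events_total, k)
  }
})

test_that("event counts are symmetric under genome swap with labels exchanged", {
  sim <- simulate_pair(test_sim_config(
    list(sim_event("fusion"), sim_event("fission")), seed = 9
  ), sequences = FALSE)
  sa <- extract_sco_set(sim$busco_a)
  sb <- extract_sco_set(sim$busco_b)
  ab <- event_report(build_links(sa, sb))
  ba <- event_report(build_links(sb, sa))
  expect_equal(ab$n_fusions_in_a, ba$n_fissions_in_a)
  expect_equal(ab$n_fissions_in_a, ba$n_fusions_in_a)
  expect_equal(ab$n_complex, ba$n_complex)
  expect_equal(ab$n_events_total, ba$n_events_total)
})

test_that("chromosome coverage is partitioned over components; unlinked listed", {
  links <- make_links(
    chrom_a = c("c1", "c1", "c2", "c2"),
    chrom_b = c("d1", "d1", "d2", "d2")
  )
  rep <- event_report(links, chroms_a = c("c1", "c2", "c3"),
                      chroms_b = c("d1", "d2"))
  expect_equal(sum(rep$components$n_chrom_a), 2)
  expect_equal(rep$unlinked_a, "c3")
  expect_equal(rep$unlinked_b, character())
})

test_that("raising min_links never increases surviving edges", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    links <- make_links(
      chrom_a = sample(paste0("c", 1:5), n, TRUE),
      chrom_b = sample(paste0("d", 1:5), n, TRUE),
      start_a = sample.int(1e5, n)
    )
    n_edges <- vapply(1:6, function(m)
      nrow(build_graph(filter_single_relocations(links, m))$edges), integer(1))
    expect_true(all(diff(n_edges) <= 0))
  }
})

test_that("the event TSV and printed summary reflect the component table", {
  links <- make_links(
    chrom_a = c("c1", "c1", "c2", "c2"),
    chrom_b = c("d1", "d1", "d1", "d1")
  )
  rep <- event_report(links)
  expect_equal(rep$n_fissions_in_a, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_tsv(rep, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(back$classification, "fission_in_a")
  expect_equal(back$n_links, 4)
  expect_true(any(grepl("fissions in A: 1", format(rep))))
})
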