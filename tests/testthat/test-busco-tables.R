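write_table_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("the seven-column dialect parses with direct field mapping", {
  path <- write_table_lines(c(
    "# BUSCO version is: 2.0.1",
    "BUSCOa\tComplete\tchr1\t100\t200\t500.1\t101",
    "BUSCOb\tMissing",
    "BUSCOc\tFragmented\tchr2\t5\t50\t22.0\t46"
  ))
  tbl <- parse_full_table(path)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$scaffold_id[1], "chr1")
  expect_equal(tbl$start[1], 100)
  expect_equal(tbl$end[1], 200)
  expect_equal(tbl$score[1], 500.1)
  expect_true(is.na(tbl$strand[1]))
  expect_true(is.na(tbl$start[2]))
})

test_that("the strand-column dialect is autodetected and extras ignored", {
  path <- write_table_lines(c(
    "# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength",
    "BUSCOa\tComplete\tchr1\t100\t200\t-\t500.1\t101\thttps://example.org\tsome description",
    "BUSCOd\tDuplicated\tchr1\t900\t990\t+\t100.0\t91",
    "BUSCOd\tDuplicated\tchr3\t10\t100\t+\t99.0\t91"
  ))
  tbl <- parse_full_table(path)
  expect_equal(tbl$strand, c("-", "+", "+"))
  expect_equal(tbl$score[1], 500.1)
  s <- busco_summary(tbl)
  expect_equal(s$n_complete, 1)
  expect_equal(s$n_duplicated, 1)
  expect_equal(s$n_total, 2)
})

test_that("parse errors carry line numbers; start > end rows are normalized", {
  bad_status <- write_table_lines(c("BUSCOa\tComplet\tchr1\t1\t2\t3\t2"))
  expect_error(parse_full_table(bad_status), "line 1", class = "bsyn_parse_error")

  bad_coord <- write_table_lines(c(
    "# comment",
    "BUSCOa\tComplete\tchr1\tabc\t200\t500.1\t101"
  ))
  expect_error(parse_full_table(bad_coord), "line 2", class = "bsyn_parse_error")

  swapped <- write_table_lines(c("BUSCOa\tComplete\tchr1\t200\t100\t500.1\t101"))
  expect_message(tbl <- parse_full_table(swapped), "swapping")
  expect_equal(c(tbl$start, tbl$end), c(100, 200))
})

test_that("status summary partitions the catalog", {
  tbl <- dplyr::bind_rows(
    busco_row("a", "Complete", "c1", 1, 10),
    busco_row("b", "Duplicated", "c1", 1, 10),
    busco_row("b", "Duplicated", "c2", 1, 10),
    busco_row("c", "Fragmented", "c1", 20, 25),
    busco_row("d", "Missing")
  )
  s <- busco_summary(tbl)
  expect_equal(s$n_complete + s$n_duplicated + s$n_fragmented + s$n_missing,
               s$n_total)
  expect_equal(s$n_total, 4)
})

test_that("revcomp remapping is an involution that preserves interval length", {
  lens <- c(chr1 = 100)
  r <- remap_revcomp(busco_row("a", "Complete", "chr1", 10, 20), lens)
  expect_equal(c(r$start, r$end), c(81, 91))
  expect_equal(r$source_direction, "revcomp")

  full <- remap_revcomp(busco_row("a", "Complete", "chr1", 1, 100), lens)
  expect_equal(c(full$start, full$end), c(1, 100))

  set.seed(51)
  L <- sample(50:5000, 200, replace = TRUE)
  s <- vapply(L, function(l) sample.int(l, 1), integer(1))
  e <- pmin(L, s + vapply(L - s, function(m) sample.int(m + 1, 1) - 1L, integer(1)))
  tbl <- busco_row(sprintf("b%03d", 1:200), "Complete", "x", 1, 1)
  tbl$start <- as.numeric(s); tbl$end <- as.numeric(e)
  tbl$scaffold_id <- sprintf("sc%03d", 1:200)
  lens <- stats::setNames(as.numeric(L), tbl$scaffold_id)
  once <- remap_revcomp(tbl, lens)
  expect_equal(once$end - once$start, tbl$end - tbl$start)
  expect_equal(remap_revcomp(once, lens), tbl)

  expect_error(remap_revcomp(busco_row("a", "Complete", "chr1", 90, 120),
                             c(chr1 = 100)),
               class = "bsyn_coordinate_error")
})

test_that("merging keeps the better status and prefers forward on ties", {
  lens <- c(chr1 = 1000, chr2 = 500)
  fwd <- dplyr::bind_rows(
    busco_row("a", "Missing"),
    busco_row("b", "Complete", "chr1", 100, 200, score = 10),
    busco_row("c", "Fragmented", "chr2", 5, 50)
  )
  rc <- dplyr::bind_rows(
    busco_row("a", "Complete", "chr1", 901, 950, score = 5),
    busco_row("b", "Complete", "chr2", 10, 110, score = 9),
    busco_row("c", "Missing")
  )
  merged <- merge_runs(fwd, rc, lens)
  a <- merged[merged$busco_id == "a", ]
  expect_equal(a$status, "Complete")
  expect_equal(c(a$start, a$end), c(1000 - 950 + 1, 1000 - 901 + 1))
  expect_equal(a$source_direction, "revcomp")
  # tie on 'b': forward kept
  expect_equal(merged$scaffold_id[merged$busco_id == "b"], "chr1")
  # 'c' keeps the forward Fragmented over revcomp Missing
  expect_equal(merged$status[merged$busco_id == "c"], "Fragmented")

  s_f <- busco_summary(fwd); s_m <- busco_summary(merged)
  expect_gte(s_m$n_complete, s_f$n_complete)
  expect_lte(s_m$n_missing, s_f$n_missing)
  expect_equal(s_m$n_complete - s_f$n_complete, 1) # the revcomp-only gain
})

test_that("ids present in one run only are treated as Missing with a warning", {
  lens <- c(chr1 = 100)
  fwd <- busco_row("a", "Complete", "chr1", 1, 10)
  rc <- busco_row("b", "Complete", "chr1", 1, 10)
  expect_warning(merged <- merge_runs(fwd, rc, lens), "one run only")
  expect_setequal(merged$busco_id, c("a", "b"))
  expect_equal(sort(merged$status), c("Complete", "Complete"))
})

test_that("the SCO set keeps exactly the Complete single-copy placements", {
  tbl <- dplyr::bind_rows(
    busco_row("a", "Complete", "c1", 1, 10),
    busco_row("b", "Duplicated", "c1", 1, 10),
    busco_row("b", "Duplicated", "c2", 1, 10),
    busco_row("c", "Fragmented", "c1", 20, 25),
    busco_row("d", "Missing")
  )
  sco <- extract_sco_set(tbl)
  expect_equal(sco$busco_id, "a")
  expect_equal(nrow(extract_sco_set(empty_tbl <- tbl[0, ])), 0)

  broken <- dplyr::bind_rows(
    busco_row("a", "Complete", "c1", 1, 10),
    busco_row("a", "Complete", "c2", 1, 10)
  )
  expect_error(extract_sco_set(broken), class = "bsyn_integrity_error")
})
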