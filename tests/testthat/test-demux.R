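test_that("reads are sliced into barcode, UMI and insert per layout", {
  layout <- read_layout(barcode_start = 0, barcode_length = 8,
                        umi_start = 8, umi_length = 8,
                        library_kind = "mRNA", min_insert_length = 4)
  reads <- toy_reads(c("ACGTACGTAAAACCCCTTTTGGGGTTTT",  # full structure
                       "ACGTACGTAA",                     # too short for UMI
                       "ACGTACGTAAAACCCCTTT"))           # insert below minimum
  tg <- parse_reads(reads, layout)
  expect_equal(tg$cell_barcode[1], "ACGTACGT")
  expect_equal(tg$umi[1], "AAAACCCC")
  expect_equal(tg$insert[1], "TTTTGGGGTTTT")
  expect_equal(tg$status, c("parsed", "too_short", "too_short"))
})

test_that("malformed records are format errors naming the record", {
  layout <- read_layout(barcode_length = 4, umi_start = 4, umi_length = 4,
                        library_kind = "mRNA", min_insert_length = 1)
  bad <- data.frame(read_id = "readX", seq = "ACGTACGTAAAA", qual = "III")
  expect_error(parse_reads(bad, layout), "readX")
  bad2 <- data.frame(read_id = "", seq = "ACGTACGTAAAA",
                     qual = strrep("I", 12))
  expect_error(parse_reads(bad2, layout), "empty read id")
})

test_that("barcode assignment handles exact, correctable and ambiguous cases", {
  wl <- barcode_whitelist(c("AAAA", "CCCC", "GGGG", "TTTT"))
  res <- assign_barcodes(c("AAAA", "AAAT", "AACT"), wl, max_mismatch = 1)
  expect_equal(res$cell, c("AAAA", "AAAA", NA))
  expect_equal(res$status, c("assigned", "assigned", "unassigned_barcode"))

  wl2 <- barcode_whitelist(c("AAAA", "AAAT"))
  res2 <- assign_barcodes("AAAC", wl2, max_mismatch = 1)
  expect_equal(res2$status, "ambiguous_barcode")
  expect_true(is.na(res2$cell))

  expect_error(assign_barcodes("AAA", wl, 1), "length")
})

test_that("barcode assignment agrees with an exhaustive Hamming oracle", {
  set.seed(71)
  for (trial in 1:40) {
    wl <- unique(rand_dna(12, 6))
    queries <- c(rand_dna(40, 6), sample(wl, 10, replace = TRUE))
    got <- assign_barcodes(queries, barcode_whitelist(wl), max_mismatch = 1)
    want <- vapply(queries, oracle_assign, character(1),
                   whitelist = wl, max_mismatch = 1, USE.NAMES = FALSE)
    expect_equal(ifelse(got$status == "assigned", got$cell,
                        ifelse(got$status == "ambiguous_barcode",
                               "ambiguous", NA_character_)),
                 want)
  }
})

test_that("zero-mismatch assignments are a subset of one-mismatch assignments", {
  set.seed(5)
  wl <- barcode_whitelist(unique(rand_dna(20, 8)))
  queries <- rand_dna(300, 8)
  a0 <- assign_barcodes(queries, wl, max_mismatch = 0)
  a1 <- assign_barcodes(queries, wl, max_mismatch = 1)
  assigned0 <- which(a0$status == "assigned")
  expect_true(all(a1$status[assigned0] == "assigned"))
  expect_equal(a0$cell[assigned0], a1$cell[assigned0])
})

test_that("adapter trimming removes leftmost adapter occurrence", {
  res <- trim_adapter3("ACGTACGTTGGAATTC", "TGGAATTC",
                       min_overlap = 5, max_err = 0)
  expect_equal(res$insert, "ACGTACGT")
  expect_true(res$trimmed)

  res2 <- trim_adapter3("ACGTACGT", "TGGAATTC", min_overlap = 5, max_err = 0)
  expect_equal(res2$insert, "ACGTACGT")
  expect_false(res2$trimmed)

  res3 <- trim_adapter3("TGGAATTCAAA", "TGGAATTC", min_overlap = 5, max_err = 0)
  expect_equal(res3$insert, "")

  # one mismatch inside the adapter occurrence still trims
  res4 <- trim_adapter3("ACGTACGTTGGTATTC", "TGGAATTC",
                        min_overlap = 5, max_err = 1)
  expect_equal(res4$insert, "ACGTACGT")

  # adapter prefix overlapping the read end, above min_overlap
  res5 <- trim_adapter3("ACGTACGTTGGAA", "TGGAATTC",
                        min_overlap = 5, max_err = 0)
  expect_equal(res5$insert, "ACGTACGT")
})

test_that("downsampling is deterministic, capped and empty-safe", {
  tagged <- data.frame(read_id = sprintf("r%d", 1:1000), x = rnorm(1000))
  s1 <- downsample_reads(tagged, 100, seed = 7)
  s2 <- downsample_reads(tagged, 100, seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100)
  s3 <- downsample_reads(tagged, 100, seed = 8)
  expect_false(identical(s1$read_id, s3$read_id))
  expect_equal(nrow(downsample_reads(tagged, 2000, seed = 1)), 1000)
  expect_equal(nrow(downsample_reads(tagged, 0, seed = 1)), 0)
})

test_that("demultiplexing conserves reads across status classes and is order-independent", {
  sc <- synthetic_scenario(n_types = 2, n_cells_per_type = 8, n_mirna = 20,
                           n_mrna = 30, n_signature_mirna = 4,
                           n_signature_mrna = 5, repression = NULL,
                           libsize_mirna = c(meanlog = log(40), sdlog = 0.2),
                           libsize_mrna = c(meanlog = log(40), sdlog = 0.2),
                           n_indices = 6, n_multimap_pairs = 0, seed = 11)
  truth <- simulate_expression(sc)
  sim <- simulate_reads(truth, sc)
  tg <- suppressMessages(demux_reads(sim$reads_smallrna, sc$layout_smallrna,
                                     sc$whitelist))
  expect_equal(sum(status_summary(tg)$n), nrow(sim$reads_smallrna))
  expect_true(all(tg$status %in% c("assigned", "unassigned_barcode",
                                   "ambiguous_barcode", "too_short",
                                   "untrimmed")))
  # permuting input reads permutes but does not change per-cell read sets
  perm <- sample(nrow(sim$reads_smallrna))
  tg2 <- suppressMessages(demux_reads(sim$reads_smallrna[perm, ],
                                      sc$layout_smallrna, sc$whitelist))
  sets1 <- split(tg$read_id[tg$status == "assigned"],
                 tg$cell[tg$status == "assigned"])
  sets2 <- split(tg2$read_id[tg2$status == "assigned"],
                 tg2$cell[tg2$status == "assigned"])
  expect_equal(lapply(sets1, sort), lapply(sets2, sort))
})

test_that("whitelist files round-trip and reject malformed input", {
  wl <- barcode_whitelist(c("ACGT", "TTTT"))
  p <- tempfile(fileext = ".txt")
  write_barcode_whitelist(wl, p)
  writeLines(c("# comment", readLines(p), ""), p)
  expect_equal(read_barcode_whitelist(p)$barcodes, wl$barcodes)
  expect_error(barcode_whitelist(c("ACGT", "ACGT")), "duplicate")
  expect_error(barcode_whitelist(c("ACGT", "ACG")), "length")
  expect_error(barcode_whitelist("ACGN"), "alphabet")
})
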