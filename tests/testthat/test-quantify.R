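test_that("UMI collapsing merges one-mismatch neighbours into components", {
  res <- collapse_umis(c("AAAA", "AAAA", "AAAT", "CCCC"))
  expect_equal(res$n, 2L)
  expect_equal(unname(res$representative[c("AAAA", "AAAT", "CCCC")]),
               c("AAAA", "AAAA", "CCCC"))
  expect_equal(collapse_umis(character())$n, 0L)
  expect_equal(collapse_umis(c("AAAA", "AAAA", "AAAA"))$n, 1L)
  expect_error(collapse_umis(c("AAAA", "AAA")), "length")
})

test_that("UMI collapse matches a brute-force connected-components oracle", {
  set.seed(19)
  for (trial in 1:200) {
    # small alphabet-biased UMIs so components actually merge
    u <- vapply(seq_len(sample(1:20, 1)), function(i)
      paste(sample(c("A", "C"), 6, replace = TRUE), collapse = ""),
      character(1))
    expect_equal(collapse_umis(u)$n, oracle_umi_count(u))
  }
})

test_that("collapse with distance 0 yields at least as many UMIs as distance 1", {
  set.seed(23)
  for (trial in 1:50) {
    u <- vapply(seq_len(30), function(i)
      paste(sample(c("A", "C", "G"), 5, replace = TRUE), collapse = ""),
      character(1))
    expect_gte(collapse_umis(u, max_dist = 0)$n,
               collapse_umis(u, max_dist = 1)$n)
  }
})

test_that("counting splits each collapsed UMI's unit mass across its features", {
  asg <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    cell = "cellA",
    umi = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT"),
    features = c("G1,G2", "G1", "G1", "G1"),
    n_locations = c(2L, 1L, 1L, 1L))
  em <- count_expression(asg, library_kind = "mRNA")
  expect_equal(em$values["cellA", "G1"], 3 + 0.5)
  expect_equal(em$values["cellA", "G2"], 0.5)
  expect_equal(sum(em$values), 4)          # 4 collapsed UMIs, unit mass each
})

test_that("total matrix mass equals the number of collapsed UMIs", {
  set.seed(31)
  cells <- sprintf("c%02d", 1:12)
  feats <- sprintf("g%02d", 1:15)
  n <- 400
  fsets <- vapply(seq_len(n), function(i)
    paste(sort(sample(feats, sample(1:3, 1))), collapse = ","), character(1))
  asg <- data.frame(read_id = sprintf("r%04d", 1:n),
                    cell = sample(cells, n, replace = TRUE),
                    umi = rand_dna(n, 4),       # short UMIs force collisions
                    features = fsets,
                    n_locations = lengths(strsplit(fsets, ",")) + 1L)
  em <- count_expression(asg, library_kind = "mRNA")
  dt <- data.table::as.data.table(asg)
  n_umis <- sum(dt[, collapse_umis(umi)$n, by = c("cell", "features")]$V1)
  expect_equal(sum(em$values), n_umis, tolerance = 1e-9)
})

test_that("counting is order-independent over the assignment stream", {
  set.seed(37)
  asg <- data.frame(read_id = sprintf("r%03d", 1:100),
                    cell = sample(c("a", "b"), 100, replace = TRUE),
                    umi = rand_dna(100, 5),
                    features = sample(c("G1", "G2", "G1,G2"), 100, TRUE),
                    n_locations = 1L)
  em1 <- count_expression(asg, "smallRNA")
  em2 <- count_expression(asg[sample(100), ], "smallRNA")
  expect_equal(as.matrix(em1$values), as.matrix(em2$values))
})

test_that("log-normalization follows ln(1 + v*scale/total) and is scale invariant", {
  v <- matrix(c(1, 9999, 0, 20), 1, 4,
              dimnames = list("c1", paste0("g", 1:4)))
  v[1, 2] <- 1e4 - 1 - 0 - 20                   # cell total exactly 10000
  em <- expression_matrix(v, "mRNA", "raw")
  ln <- normalize_lognorm(em, scale_factor = 1e4)
  expect_equal(ln$values["c1", "g1"], log(2))
  expect_equal(ln$values["c1", "g3"], 0)
  # multiplying all counts of a cell by 4 changes nothing
  em4 <- expression_matrix(v * 4, "mRNA", "raw")
  expect_equal(as.matrix(normalize_lognorm(em4)$values), as.matrix(ln$values))
  # state machine: re-normalizing is rejected
  expect_error(normalize_lognorm(ln), "already normalized")
})

test_that("zero-total cells are dropped with a warning, or error in strict mode", {
  v <- matrix(c(5, 0, 3, 0), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  em <- expression_matrix(v, "mRNA", "raw")
  expect_warning(ln <- normalize_lognorm(em), "zero total")
  expect_equal(rownames(ln$values), "c1")
  expect_error(normalize_lognorm(em, strict = TRUE), "zero total")
})

test_that("log2-RPM arithmetic and invariances hold", {
  v <- c(a = 1023, b = 0)
  v2 <- c(v, c = 1e6 - 1023)
  out <- normalize_log2rpm(v2)
  expect_equal(unname(out["a"]), 10)
  expect_equal(unname(out["b"]), 0)
  expect_equal(normalize_log2rpm(v2 * 2), out)
  expect_error(normalize_log2rpm(c(0, 0)), "positive")
})

test_that("group aggregation averages per group and checks the label map", {
  v <- matrix(c(2, 4, 10), 3, 1, dimnames = list(c("c1", "c2", "c3"), "f"))
  em <- expression_matrix(v, "mRNA", "raw")
  agg <- aggregate_by_group(em, c(c1 = "A", c2 = "A", c3 = "B"))
  expect_equal(agg["A", "f"], 3)
  expect_equal(agg["B", "f"], 10)
  expect_error(aggregate_by_group(em, c(c1 = "A", c2 = "A")), "missing")
  expect_error(aggregate_by_group(em, c(c1 = "A", c2 = "A", c3 = "A",
                                        ghost = "B")), "empty group")
})

test_that("top-expressed selection keeps n features with lexicographic ties", {
  m <- matrix(c(5, 5, 3, 1), 1, 4,
              dimnames = list("g", c("fb", "fa", "fc", "fd")))
  out <- select_top_expressed(m, 3)
  expect_setequal(colnames(out), c("fa", "fb", "fc"))
  m2 <- matrix(c(1, 1), 1, 2, dimnames = list("g", c("zz", "aa")))
  expect_equal(colnames(select_top_expressed(m2, 1)), "aa")
  expect_equal(ncol(select_top_expressed(m, 99)), 4)
})

test_that("small-RNA matcher reports all prefix matches and multimaps families", {
  ref <- c("miR-1" = "ACGTACGTACGTACGTACGTAC",
           "miR-2" = "TTTTCCCCGGGGAAAATTTTCC",
           "miR-2b" = "TTTTCCCCGGGGAAAATTTTCC")   # identical family member
  tg <- data.frame(read_id = c("r1", "r2", "r3"),
                   cell = "c1", umi = c("AAAA", "CCCC", "GGGG"),
                   insert = c("ACGTACGTACGTACGTACGTAC",  # exact
                              "TTTTCCCCGGGGAAAATTTTCC",  # family, 2 ids
                              "GGGGGGGGGGGGGGGGGGGGGG"), # far from everything
                   status = "assigned")
  asg <- suppressMessages(assign_smallrna_features(tg, ref, max_mismatch = 1))
  expect_equal(asg$features[asg$read_id == "r1"], "miR-1")
  expect_equal(asg$n_locations[asg$read_id == "r1"], 1L)
  expect_equal(asg$features[asg$read_id == "r2"], "miR-2,miR-2b")
  expect_equal(asg$n_locations[asg$read_id == "r2"], 2L)
  expect_false("r3" %in% asg$read_id)
  # distance-2 insert stays unassigned under max_mismatch = 1
  tg2 <- tg[1, ]
  tg2$insert <- sub("^AC", "TG", tg2$insert)
  expect_equal(nrow(suppressMessages(
    assign_smallrna_features(tg2, ref, max_mismatch = 1))), 0)
  expect_error(assign_smallrna_features(tg, c(a = "ACGT", a = "ACGG")),
               "duplicate")
})

test_that("alignment ingestion joins on read id and flags orphans", {
  tg <- data.frame(read_id = c("r1", "r2", "r3"), cell = c("c1", "c1", "c2"),
                   umi = c("AAAA", "CCCC", "GGGG"), insert = "NNNN",
                   status = c("assigned", "assigned", "assigned"))
  aln <- data.frame(read_id = c("r1", "r2"),
                    features = c("G1", "G2,G1"),
                    n_locations = c(1L, 3L))
  asg <- suppressMessages(ingest_alignments(aln, tg))
  expect_equal(nrow(asg), 2)
  expect_equal(asg$features[asg$read_id == "r2"], "G1,G2")
  expect_equal(asg$n_locations[asg$read_id == "r2"], 3L)
  orphan <- rbind(aln, data.frame(read_id = "ghost", features = "G3",
                                  n_locations = 1L))
  expect_error(ingest_alignments(orphan, tg), "ghost")
})

test_that("expression matrices round-trip through MatrixMarket sidecar files", {
  v <- matrix(c(0, 1.5, 2, 0), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  em <- expression_matrix(v, "smallRNA", "raw")
  d <- tempfile("mtx")
  write_expression_matrix(em, d)
  back <- read_expression_matrix(d)
  expect_equal(as.matrix(back$values), as.matrix(em$values))
  expect_equal(back$library_kind, "smallRNA")
  expect_equal(back$normalization, "raw")
})

test_that("SAM alignments convert to the tabular alignment format", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:G1\tLN:1000",
    "@SQ\tSN:G2\tLN:1000",
    "r1\t0\tG1\t10\t255\t10M\t*\t0\t0\tACGTACGTAC\t*\tNH:i:1",
    "r2\t0\tG1\t20\t255\t10M\t*\t0\t0\tACGTACGTAC\t*\tNH:i:3",
    "r2\t256\tG2\t30\t255\t10M\t*\t0\t0\tACGTACGTAC\t*\tNH:i:3",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*"), sam)
  aln <- read_alignments_bam(sam)
  aln <- aln[order(aln$read_id), ]
  expect_equal(aln$read_id, c("r1", "r2"))
  expect_equal(aln$features, c("G1", "G1,G2"))
  expect_equal(aln$n_locations, c(1L, 3L))
})
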