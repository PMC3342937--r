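test_that("load_annotation converts GFF3 to the 0-based half-open frame", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\ttransposable_element\t301\t400\t.\t-\t.\tID=te1",
    "chr1\tsrc\texotic_thing\t501\t550\t.\t.\t.\tID=x1"), path)
  f <- load_annotation(path, "gff3")
  expect_equal(f$start, c(100, 300, 500))
  expect_equal(f$end, c(200, 400, 550))
  expect_equal(f$category, c("gene", "TE", "other"))
  expect_equal(f$strand, c("+", "-", "."))
  expect_equal(f$id, c("g1", "te1", "x1"))
})

test_that("load_annotation: BED passes through half-open and empty files work", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tg1\t0\t-", bed)
  f <- load_annotation(bed, "bed", category_map = c(g1 = "gene"))
  expect_equal(f[, .(chrom, start, end, strand, category)],
               data.table::data.table(chrom = "chr1", start = 99, end = 200,
                                      strand = "-", category = "gene"))
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(load_annotation(empty, "gff3")), 0L)
})

test_that("load_annotation reports malformed lines with their line number", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\tnot_a_number\t300"), bad)
  expect_error(load_annotation(bad, "gff3"), "line 3")
  rev_coords <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\tsrc\tgene\t500\t100\t.\t+\t.\tID=g1", rev_coords)
  expect_error(load_annotation(rev_coords, "gff3"), "end < start")
})

test_that("inter-annotation regions match the union-complement oracle", {
  gm <- genome_model(data.frame(name = "c1", length = 1000))
  feats <- feature_table(c("a", "b"), "c1", c(100, 400), c(200, 500),
                         "+", "gene")
  irs <- compute_inter_annotation_regions(feats, gm, min_len = 150)
  expect_equal(irs[, .(start, end)],
               data.table::data.table(start = c(200, 500), end = c(400, 1000)))
  # full complement (min_len = 0) includes [0,100)
  irs0 <- compute_inter_annotation_regions(feats, gm, min_len = 0)
  expect_equal(irs0$start, c(0, 200, 500))

  # overlapping features are unioned first
  ov <- feature_table(c("a", "b"), "c1", c(0, 200), c(300, 600), "+", "gene")
  expect_equal(compute_inter_annotation_regions(ov, gm, 150)[, .(start, end)],
               data.table::data.table(start = 600, end = 1000))

  # tiling features leave no IRs
  tile <- feature_table(c("a", "b"), "c1", c(0, 500), c(500, 1000), "+",
                        "gene")
  expect_equal(nrow(compute_inter_annotation_regions(tile, gm, 150)), 0L)
})

test_that("IR complement property holds on random toy genomes", {
  for (trial in 1:10) {
    with_seed(100 + trial, {
      len <- sample(2000:10000, 1)
      gm <- genome_model(data.frame(name = "c1", length = len))
      n <- sample(3:12, 1)
      s <- sort(sample(0:(len - 50), n))
      e <- pmin(len, s + sample(30:500, n, replace = TRUE))
      feats <- feature_table(sprintf("f%d", 1:n), "c1", s, e, "+", "gene")
      irs <- compute_inter_annotation_regions(feats, gm, min_len = 0)
      orc <- oracle_complement(s, e, len)
      expect_equal(irs$start, orc$start)
      expect_equal(irs$end, orc$end)
      # per-base cover: features union + IRs cover every base exactly once
      cov <- integer(len)
      for (i in seq_len(nrow(orc)))
        cov[(orc$start[i] + 1):orc$end[i]] <- cov[(orc$start[i] + 1):orc$end[i]] + 1L
      red <- IRanges::reduce(IRanges::IRanges(s + 1, e))
      for (i in seq_along(red))
        cov[IRanges::start(red)[i]:IRanges::end(red)[i]] <-
          cov[IRanges::start(red)[i]:IRanges::end(red)[i]] + 1L
      expect_true(all(cov == 1L))
    })
  }
})

test_that("chromatin-state merging collapses abutting same-state runs only", {
  seg <- data.frame(chrom = "c1", start = c(0, 100), end = c(100, 250),
                    state = c("CS1", "CS1"))
  m <- merge_adjacent_state_segments(seg)
  expect_equal(nrow(m), 1L)
  expect_equal(m$end, 250)

  seg2 <- data.frame(chrom = "c1", start = c(0, 100), end = c(100, 250),
                     state = c("CS1", "CS2"))
  expect_equal(nrow(merge_adjacent_state_segments(seg2)), 2L)

  # random abutting segments match the linear-scan oracle; idempotent
  for (trial in 1:5) {
    with_seed(200 + trial, {
      brk <- sort(sample(1:999, 9))
      seg <- data.frame(chrom = "c1", start = c(0, brk), end = c(brk, 1000),
                        state = sample(paste0("CS", 1:2), 10, replace = TRUE))
      m <- merge_adjacent_state_segments(seg)
      o <- oracle_merge_states(seg)
      expect_equal(as.data.frame(m), o, ignore_attr = TRUE)
      expect_equal(merge_adjacent_state_segments(m), m)
      expect_lte(nrow(m), nrow(seg))
    })
  }

  ovl <- data.frame(chrom = "c1", start = c(0, 50), end = c(100, 150),
                    state = c("CS1", "CS1"))
  expect_error(merge_adjacent_state_segments(ovl), "overlapping")
})

test_that("gene filters record reasons and are order-independent", {
  feats <- feature_table(
    id = c("g_short", "g_org", "g_ovl", "g_ok", "te1"),
    chrom = c("c1", "ChrM", "c1", "c1", "c1"),
    start = c(0, 0, 2000, 8000, 3900),
    end = c(900, 5000, 4000, 10000, 4500),
    strand = "+",
    category = c("gene", "gene", "gene", "gene", "TE"))
  genes <- feats[category == "gene"]
  res <- filter_genes_for_profiles(genes, feats)
  expect_equal(res$kept$id, "g_ok")
  expect_equal(res$excluded[order(id)],
               data.table::data.table(
                 id = c("g_org", "g_ovl", "g_short"),
                 reason = c("organellar", "overlap", "short")))
  # permuting input order changes nothing
  perm <- genes[c(3, 1, 4, 2)]
  res2 <- filter_genes_for_profiles(perm, feats)
  expect_setequal(res2$kept$id, res$kept$id)
  expect_equal(res2$excluded[order(id)], res$excluded[order(id)])
})

test_that("genes overlapping each other are excluded, IRs never count", {
  feats <- feature_table(
    id = c("g1", "g2", "ir1"),
    chrom = "c1", start = c(0, 1500, 3000), end = c(2000, 3000, 5000),
    strand = c("+", "-", "."),
    category = c("gene", "gene", "IR"))
  res <- filter_genes_for_profiles(feats[category == "gene"], feats)
  expect_setequal(res$excluded$id, c("g1", "g2"))
  expect_true(all(res$excluded$reason == "overlap"))
})
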