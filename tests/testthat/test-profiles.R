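test_that("sliding_mean: identity, worked example, edges, errors", {
  expect_equal(sliding_mean(c(4, 7, 1), 1), c(4, 7, 1))
  expect_equal(sliding_mean(c(1, 2, 3, 4), 3), c(1.5, 2, 3, 3.5))
  expect_equal(sliding_mean(rep(2.5, 9), 5), rep(2.5, 9))
  expect_error(sliding_mean(1:3, 7), "twice")
  expect_error(sliding_mean(1:3, 0), "positive")
  # NA positions are skipped (window shrinks over them)
  expect_equal(sliding_mean(c(1, NA, 3), 3), c(1, 2, 3))
  # random series match the loop oracle, odd and even windows
  with_seed(77, {
    for (w in c(2, 3, 6)) {
      x <- runif(25)
      expect_equal(sliding_mean(x, w), oracle_sliding_mean(x, w),
                   tolerance = 1e-12)
    }
  })
})

test_that("point profiles: uniform flat, identity smoothing, errors", {
  gm <- toy_genome(c(c1 = 10000))
  u <- uniform_track(gm, 1)
  anch <- data.frame(chrom = "c1", pos = c(3000, 5000, 7000), strand = "+")
  p <- point_anchored_profile(u, anch, bin = 100, span = 2000)
  expect_true(all(p$mean == 1))
  expect_equal(p$n, rep(3L, 20))
  expect_equal(p$offset, seq(-1000, 900, by = 100))

  rt <- random_track(gm, 3)
  single <- data.frame(chrom = "c1", pos = 5000, strand = "+")
  p1 <- point_anchored_profile(rt, single, bin = 100, span = 1000,
                               smooth = 100)
  raw <- sapply(seq(-500, 400, by = 100), function(o)
    mean_signal(rt, "c1", 5000 + o, 5000 + o + 100))
  expect_equal(p1$mean, raw, tolerance = 1e-12)

  expect_error(point_anchored_profile(u, anch, bin = 500, span = 100), "bin")
  far <- data.frame(chrom = "c1", pos = 0, strand = "+")
  expect_error(point_anchored_profile(u, far, bin = 40000, span = 40000),
               "clipped")
})

test_that("point profiles match the brute-force oracle incl. strand and clipping", {
  gm <- toy_genome(c(c1 = 20000, c2 = 15000))
  rt <- random_track(gm, 13)
  with_seed(21, {
    anch <- data.frame(
      chrom = sample(c("c1", "c2"), 20, replace = TRUE),
      pos = sample(200:14000, 20),  # some windows will clip
      strand = sample(c("+", "-"), 20, replace = TRUE))
  })
  p <- point_anchored_profile(rt, anch, bin = 50, span = 2000, smooth = 50)
  o <- oracle_point_profile(rt, anch, bin = 50, span = 2000)
  expect_equal(p$mean, o$mean, tolerance = 1e-9)
  expect_equal(p$n, o$n)
})

test_that("half-gene profiles: flat on uniform tracks, strand symmetric", {
  gm <- toy_genome(c(c1 = 10000))
  u <- uniform_track(gm, 2.5)
  genes <- feature_table(c("a", "b"), "c1", c(1000, 6000), c(3000, 8500),
                         c("+", "-"), "gene")
  p <- halfgene_profile(u, genes, bin = 50, max_extent = 1000, smooth = 50)
  expect_true(all(abs(p$mean - 2.5) < 1e-12))
  expect_equal(sort(unique(as.character(p$segment))), c("3half", "5half"))

  # a minus-strand mirror gene over a mirrored track samples identically
  len <- 10000
  rt <- random_track(gm, 8)
  mirror <- signal_track(list(c1 = rev(rt$values$c1)), step = 10,
                         library_size = 1e6, normalized = TRUE)
  gplus <- feature_table("g", "c1", 2000, 4600, "+", "gene")
  gminus <- feature_table("g", "c1", len - 4600, len - 2000, "-", "gene")
  pp <- halfgene_profile(rt, gplus, bin = 50, max_extent = 1500, smooth = 50)
  pm <- halfgene_profile(mirror, gminus, bin = 50, max_extent = 1500,
                         smooth = 50)
  expect_equal(pp$mean, pm$mean, tolerance = 1e-12)
  expect_equal(pp$offset, pm$offset)
})

test_that("half-gene profiles match the per-gene oracle with flanks", {
  gm <- toy_genome(c(c1 = 60000))
  rt <- random_track(gm, 17)
  with_seed(55, {
    starts <- sort(sample(seq(500, 55000, by = 1800), 25))
    lens <- sample(seq(600, 3400, by = 100), 25, replace = TRUE)
    genes <- feature_table(sprintf("g%02d", 1:25), "c1", starts,
                           pmin(starts + lens, 59000),
                           sample(c("+", "-"), 25, TRUE), "gene")
  })
  irs <- compute_inter_annotation_regions(genes, gm, min_len = 0)
  fl <- gene_flanks(genes, irs)
  p <- suppressWarnings(
    halfgene_profile(rt, genes, fl, bin = 50, max_extent = 1000,
                     smooth = 50))
  o <- oracle_halfgene_profile(rt, as.data.frame(genes), as.data.frame(fl),
                               bin = 50, max_extent = 1000)
  expect_equal(p$segment, o$segment)
  expect_equal(p$offset, o$offset)
  expect_equal(p$mean, o$mean, tolerance = 1e-9)
  expect_equal(p$n, o$n)
})

test_that("half-gene anchor bookkeeping: n(offset) counts genes reaching it", {
  gm <- toy_genome(c(c1 = 50000))
  u <- uniform_track(gm, 1)
  lens <- c(400, 900, 1400, 2600, 3300)
  starts <- c(1000, 5000, 10000, 20000, 30000)
  genes <- feature_table(sprintf("g%d", 1:5), "c1", starts, starts + lens,
                         "+", "gene")
  p <- halfgene_profile(u, genes, bin = 50, max_extent = 5000, smooth = 50)
  half_bins <- (lens %/% 2) %/% 50
  p5 <- p[p$segment == "5half", ]
  for (k in seq_len(nrow(p5))) {
    o <- p5$offset[k]
    expect_equal(p5$n[k], sum(half_bins * 50 > o))
  }
  # genes shorter than 2*bin are skipped with a warning
  tiny <- feature_table("t", "c1", 0, 80, "+", "gene")
  expect_warning(halfgene_profile(u, rbind(genes, tiny), bin = 50,
                                  max_extent = 500, smooth = 50),
                 "skipping")
  expect_error(suppressWarnings(halfgene_profile(u, tiny, bin = 50,
                                                 max_extent = 500,
                                                 smooth = 50)),
               "empty gene set")
})
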