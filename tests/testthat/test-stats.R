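test_that("last-kb enrichment is the 3' gene-oriented window", {
  gm <- toy_genome(c(c1 = 6000))
  u <- uniform_track(gm, 2)
  g <- feature_table("g", "c1", 0, 3000, "+", "gene")
  expect_equal(last_kb_enrichment(u, g), 2)

  # ramped track: plus-strand gene [0,3000) takes bins over [2000,3000)
  vals <- list(c1 = as.numeric(1:600))
  rampt <- signal_track(vals, step = 10, library_size = 1, normalized = TRUE)
  expect_equal(last_kb_enrichment(rampt, g),
               oracle_mean_signal(rampt, "c1", 2000, 3000), tolerance = 1e-12)

  # minus-strand mirror on the mirrored track gives the identical value
  mirr <- signal_track(list(c1 = rev(vals$c1)), step = 10, library_size = 1,
                       normalized = TRUE)
  gm_minus <- feature_table("g", "c1", 3000, 6000, "-", "gene")
  expect_equal(last_kb_enrichment(mirr, gm_minus),
               last_kb_enrichment(rampt, g), tolerance = 1e-12)

  short <- feature_table("s", "c1", 0, 900, "+", "gene")
  expect_error(last_kb_enrichment(u, short), "shorter")

  # vectorized table agrees with the scalar op
  genes <- rbind(g, gm_minus)
  tab <- last_kb_enrichment_table(rampt, genes)
  expect_equal(tab$value[1], last_kb_enrichment(rampt, g))
})

test_that("Spearman: monotone, reversed, tie-averaged ranks, invariance", {
  x <- c(0.3, 1.1, 4, 9)
  expect_equal(spearman_correlation(x, exp(x)), 1.0)
  expect_equal(spearman_correlation(1:3, 3:1), -1.0)

  xt <- c(1, 1, 2, 4); yt <- c(10, 20, 20, 40)
  expect_equal(spearman_correlation(xt, yt), oracle_spearman(xt, yt),
               tolerance = 1e-12)

  with_seed(88, {
    a <- rnorm(60); b <- rnorm(60) + 0.5 * a
    rho <- spearman_correlation(a, b)
    expect_equal(spearman_correlation(exp(a), b^3 + 5 * b), rho,
                 tolerance = 1e-12)
    expect_equal(rho, oracle_spearman(a, b), tolerance = 1e-12)
  })
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("windowed scatter sorts by x and smooths both coordinates", {
  with_seed(31, {
    x <- runif(40); y <- runif(40)
  })
  s1 <- windowed_scatter(x, y, window = 1)
  o <- order(x)
  expect_equal(s1$xbar, x[o])
  expect_equal(s1$ybar, y[o])         # multiset of y conserved, sorted by x
  s2 <- windowed_scatter(x, y, window = 7)
  expect_equal(s2$xbar, oracle_sliding_mean(x[o], 7), tolerance = 1e-12)
  expect_equal(s2$ybar, oracle_sliding_mean(y[o], 7), tolerance = 1e-12)
  sc <- windowed_scatter(x, rep(3, 40), window = 5)
  expect_true(all(sc$ybar == 3))
  expect_error(windowed_scatter(x, y, window = 41), "exceed")
})

test_that("differential rank scatter: diagonal, flat null, full window", {
  with_seed(62, {
    d <- rnorm(300)
    names(d) <- sprintf("g%03d", 1:300)
    same <- differential_rank_scatter(d, d, window = 25)
    expect_equal(same$expr_rank, same$enr_rank, tolerance = 1e-12)

    # independent enrichment: smoothed rank hovers near the center
    e <- setNames(rnorm(2000), sprintf("h%04d", 1:2000))
    f <- setNames(rnorm(2000), sample(names(e)))
    rs <- differential_rank_scatter(e, f, window = 500)
    center <- (2000 + 1) / 2
    expect_lt(max(abs(rs$enr_rank - center)), 0.25 * 2000)

    # a full-coverage window averages every rank: (n+1)/2
    small <- setNames(rnorm(21), sprintf("s%02d", 1:21))
    oth <- setNames(rnorm(21), names(small))
    full <- differential_rank_scatter(small, oth, window = 21)
    expect_equal(full$expr_rank[11], 11)
    expect_equal(full$enr_rank[11], 11)
  })
  expect_error(differential_rank_scatter(c(a = 1, b = 2), c(a = 1, x = 2)),
               "same gene set")
})

test_that("region distributions give type-7 five-number summaries", {
  gm <- toy_genome(c(c1 = 10000))
  u <- uniform_track(gm, 4)
  regions <- feature_table(sprintf("r%d", 1:3), "c1",
                           c(0, 3000, 6000), c(1000, 4000, 7000), ".", "IR")
  d <- distribution_over_regions(u, regions, by = "category")
  expect_equal(unlist(d[, .(min, q1, median, q3, max)]), rep(4, 5),
               ignore_attr = TRUE)

  # regions engineered to have means 1..5
  vals <- list(c1 = rep(1:5, each = 100))
  tr <- signal_track(vals, step = 10, library_size = 1, normalized = TRUE)
  regs <- feature_table(sprintf("r%d", 1:5), "c1",
                        seq(0, 4000, by = 1000), seq(1000, 5000, by = 1000),
                        ".", "IR")
  d2 <- distribution_over_regions(tr, regs, by = "category")
  expect_equal(d2$q1, oracle_quantile_type7(1:5, 0.25))
  expect_equal(d2$median, 3)
  expect_equal(d2$q3, 4)
  expect_equal(d2$n, 5)

  single <- distribution_over_regions(tr, regs[1], by = "category")
  expect_equal(single$min, single$max)
  expect_warning(distribution_over_regions(tr, regs, by = "category",
                                           classes = c("IR", "gene")),
                 "gene")
})

test_that("Welch t-test matches the closed form and stats::t.test", {
  a <- c(1, 2, 3); b <- a + 100 + c(0.001, -0.001, 0)
  expect_lt(welch_t_test(a, b)$p_value, 1e-3)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)

  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  got <- welch_t_test(x, y)
  # hand evaluation: equal variances 5/3, se^2 = 2*(5/3)/4, df = 6
  se2 <- 2 * (5 / 3) / 4
  t_hand <- -1 / sqrt(se2)
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 6, tolerance = 1e-12)
  ref <- stats::t.test(x, y)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(welch_t_test(rep(1, 3), rep(2, 4)), "degenerate")
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})
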