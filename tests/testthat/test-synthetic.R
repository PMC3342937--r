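test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config(seed = 21)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_equal(a$features, b$features)
  expect_equal(a$states, b$states)
  expect_equal(as.data.table(a$expr), as.data.table(b$expr))
  expect_equal(a$tracks$dividing$H3.3[[1]]$values,
               b$tracks$dividing$H3.3[[1]]$values)
  # a different seed changes the data
  c <- generate_genome(cfg, seed = 22)
  expect_false(identical(a$features, c$features))
})

test_that("generated annotation satisfies the genome contracts", {
  cfg <- small_config(seed = 33)
  gs <- generate_genome(cfg)
  f <- gs$features
  expect_true(all(f$end > f$start))
  # no overlaps among generated features (per chromosome)
  for (cn in unique(f$chrom)) {
    sub <- f[f$chrom == cn][order(start)]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  # IR complement property on the generated genome
  irs <- compute_inter_annotation_regions(f, gs$genome, min_len = 0)
  lens <- chrom_lengths(gs$genome)
  for (cn in names(lens)) {
    tot <- sum(f[f$chrom == cn, end - start]) +
      sum(irs[irs$chrom == cn, end - start])
    expect_equal(tot, lens[[cn]])
  }
  # chromatin states tile each chromosome without overlap
  st <- gs$states
  for (cn in names(lens)) {
    s <- st[st$chrom == cn][order(start)]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], lens[[cn]])
    expect_true(all(s$start[-1] == s$end[-nrow(s)]))
  }
  # merging is already maximal
  expect_equal(merge_adjacent_state_segments(st), st)

  # n_genes = 0: only TEs and IR space remain
  gs0 <- generate_genome(small_config(seed = 5, n_genes = 0L))
  expect_equal(unique(gs0$features$category), "TE")
})

test_that("expression generator: noise, differential labels, recovery", {
  # zero replicate noise -> consistency filter keeps everything
  cfg0 <- small_config(seed = 41, replicate_sdlog = 0, frac_silent = 0)
  gs0 <- generate_genome(cfg0)
  ex0 <- generate_expression(cfg0, gs0)
  v <- filter_expression(ex0$expr)
  expect_true(all(v$keep))

  # zero differential fraction -> empty fold-change sets at zero noise
  cfgn <- small_config(seed = 42, replicate_sdlog = 0,
                       frac_differential = 0)
  gsn <- generate_genome(cfgn)
  exn <- generate_expression(cfgn, gsn)
  s <- select_fold_change_sets(expression_means(exn$expr), fold = 5)
  expect_length(s$up_in_dividing, 0)
  expect_length(s$up_in_nondividing, 0)

  # labelled >= 5-fold genes are recovered with sensitivity > 0.9
  cfg <- synthetic_config(seed = 43, n_chromosomes = 5L, chrom_length = 1e6,
                          n_genes = 1000L, replicate_sdlog = 0,
                          frac_silent = 0, frac_differential = 0.1)
  gs <- generate_genome(cfg)
  ex <- generate_expression(cfg, gs)
  sets <- select_fold_change_sets(expression_means(ex$expr), fold = 5)
  truth_up <- ex$truth$gene_id[ex$truth$label == "up_dividing"]
  truth_dn <- ex$truth$gene_id[ex$truth$label == "up_nondividing"]
  sens <- (sum(truth_up %in% sets$up_in_dividing) +
             sum(truth_dn %in% sets$up_in_nondividing)) /
    (length(truth_up) + length(truth_dn))
  expect_gt(sens, 0.9)
})

test_that("track generator encodes the deposition models", {
  # slope 0, no sampling noise -> H3.3 exactly flat outside heterochromatin
  cfg <- small_config(seed = 51, h33_slope = 0, sampling_noise = FALSE,
                      track_replicates = 1L)
  gs <- generate_genome(cfg)
  ex <- generate_expression(cfg, gs)
  tr <- generate_tracks(cfg, gs, ex$truth)
  v <- tr$dividing$H3.3[[1]]$values$Chr1
  het <- as.data.table(gs$genome$heterochromatin)[chrom == "Chr1"]
  het_bins <- unlist(lapply(seq_len(nrow(het)), function(i)
    seq(het$start[i] %/% 10 + 1, het$end[i] %/% 10)))
  eu <- setdiff(seq_along(v), het_bins)
  expect_equal(v[eu], rep(cfg$h33_baseline * cfg$depth, length(eu)),
               tolerance = 1e-12)

  # heterochromatin depletion factor is applied
  expect_equal(unique(round(v[het_bins], 9)),
               cfg$h33_baseline * cfg$h33_het_depletion * cfg$depth)

  # depletion factor 1 -> CS3 and CS1 medians indistinguishable for H3.3
  # when the slope is also 0 (no effect injected)
  cfg1 <- small_config(seed = 52, h33_slope = 0, h33_het_depletion = 1,
                       sampling_noise = FALSE, track_replicates = 1L)
  gs1 <- generate_genome(cfg1)
  ex1 <- generate_expression(cfg1, gs1)
  tr1 <- generate_tracks(cfg1, gs1, ex1$truth)
  t1 <- normalize_by_library_size(tr1$dividing$H3.3[[1]])
  d <- distribution_over_regions(t1, gs1$states, by = "state")
  expect_equal(d$median[d$class == "CS3"], d$median[d$class == "CS1"],
               tolerance = 1e-9)

  # H3 centromeric bump present; IgG flat in expectation
  th3 <- tr$dividing$H3[[1]]$values$Chr1
  cen <- as.data.table(gs$genome$centromeres)[chrom == "Chr1"]
  cen_bins <- seq(cen$start %/% 10 + 1, cen$end %/% 10)
  expect_gt(mean(th3[cen_bins]), mean(th3[-cen_bins]))
})

test_that("emitted files re-read into the same in-memory objects", {
  cfg <- small_config(seed = 61, track_replicates = 1L)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  back <- read_dataset(dir, step = cfg$step)
  expect_equal(chrom_lengths(back$genome), chrom_lengths(sim$genome))
  expect_equal(back$features, sim$features)
  expect_equal(back$states, sim$states)
  expect_equal(back$sites[, .(id, chrom, pos, strand)],
               sim$sites[, .(id, chrom, pos, strand)])
  expect_equal(as.data.table(back$expr)[order(gene_id, tissue, replicate)],
               as.data.table(sim$expr)[order(gene_id, tissue, replicate)],
               tolerance = 0)
  expect_equal(back$truth$fpkm_dividing, sim$truth$fpkm_dividing,
               tolerance = 0)
  expect_equal(back$tracks$dividing$H3.3[[1]]$values,
               sim$tracks$dividing$H3.3[[1]]$values, tolerance = 0)
  expect_equal(back$tracks$nondividing$IgG[[1]]$library_size,
               sim$tracks$nondividing$IgG[[1]]$library_size)
})
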