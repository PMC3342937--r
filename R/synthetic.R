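# Synthetic-data generator: multi-chromosome genomes with centromeres and
# heterochromatin, stranded genes separated by inter-annotation gaps,
# TE placement biased toward heterochromatin, two-tissue/two-replicate FPKM
# tables with a controlled differential fraction, and per-tissue density
# tracks for H3.3 (3'-increasing deposition scaled by expression, depleted
# in heterochromatin), H3.1 (near-uniform, mildly heterochromatin-enriched),
# H3 (uniform with a centromeric bump) and IgG (flat noise).
#
# Every generator is a pure function of (config, seed); ground truth is
# recorded for recovery tests.

#' Synthetic dataset configuration
#'
#' Defaults describe a down-scaled plant-like genome: 5 chromosomes of 1 Mb
#' with a central centromere (12% of the chromosome) and one 50-kb
#' heterochromatic knob per chromosome; 1000 genes with log-normal lengths
#' (median 1.8 kb); two tissues ("dividing", "nondividing") with two
#' replicates each, 10% of genes at least 5-fold differential; and
#' Poisson sampling noise on the 10-bp track grid.
#'
#' @param seed integer seed.
#' @param n_chromosomes,chrom_length genome shape.
#' @param centromere_fraction fraction of each chromosome occupied by the
#'   centromere block.
#' @param knob_length heterochromatic knob length in bp (0 disables).
#' @param n_genes,gene_meanlog,gene_sdlog gene count and log-normal length
#'   distribution (bp).
#' @param gap_mean,min_gap inter-annotation gap model (bp).
#' @param n_tes,te_het_bias,te_meanlog,te_sdlog TE count, fraction placed
#'   inside heterochromatin, and TE length distribution.
#' @param n_sites number of TFBS-like point sites placed in non-exonic
#'   (inter-annotation) space.
#' @param active_fraction fraction of genes in the actively-expressed class
#'   (drives CS1/CS2 labelling and the expression mixture).
#' @param frac_silent fraction of genes with FPKM 0 in all libraries.
#' @param frac_differential fraction of genes at least `fold_min`-fold
#'   differential between tissues.
#' @param fpkm_meanlog_active,fpkm_sdlog_active,fpkm_meanlog_inactive,fpkm_sdlog_inactive
#'   log-normal FPKM parameters of the two expression classes.
#' @param fold_min minimum true fold change of differential genes.
#' @param replicate_sdlog multiplicative log-normal replicate noise (sdlog).
#' @param h33_baseline,h33_slope,h33_het_depletion H3.3 deposition model:
#'   per-base density `baseline + slope * log1p(FPKM) * frac` with `frac`
#'   the fractional position 5'->3' along the gene, multiplied by the
#'   depletion factor inside heterochromatin.
#' @param h31_baseline,h31_het_enrichment H3.1 model: flat baseline, mildly
#'   enriched inside heterochromatin.
#' @param h3_baseline,h3_cen_bump H3 model: flat with a centromeric bump.
#' @param igg_level flat IgG background level.
#' @param step track grid step in bp.
#' @param depth expected Poisson counts per unit density per bin (sampling
#'   depth; larger means less noise).
#' @param sampling_noise logical; `FALSE` yields noise-free tracks.
#' @param track_replicates tracks generated per (tissue, antibody).
#' @return list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 5L, chrom_length = 1e6,
                             centromere_fraction = 0.12, knob_length = 5e4,
                             n_genes = 1000L, gene_meanlog = log(1800),
                             gene_sdlog = 0.45,
                             gap_mean = 400, min_gap = 60,
                             n_tes = 300L, te_het_bias = 0.8,
                             te_meanlog = log(1500), te_sdlog = 0.6,
                             n_sites = 2000L,
                             active_fraction = 0.6,
                             frac_silent = 0.05, frac_differential = 0.10,
                             fpkm_meanlog_active = log(10),
                             fpkm_sdlog_active = 1.0,
                             fpkm_meanlog_inactive = log(0.5),
                             fpkm_sdlog_inactive = 0.8,
                             fold_min = 5, replicate_sdlog = 0.02,
                             h33_baseline = 1, h33_slope = 0.4,
                             h33_het_depletion = 0.5,
                             h31_baseline = 1, h31_het_enrichment = 1.05,
                             h3_baseline = 1, h3_cen_bump = 1.3,
                             igg_level = 1,
                             step = 10L, depth = 50,
                             sampling_noise = TRUE,
                             track_replicates = 2L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chromosomes > 0, chrom_length > 0, n_genes >= 0, n_tes >= 0,
              centromere_fraction >= 0, centromere_fraction < 1,
              frac_silent >= 0, frac_silent <= 1,
              frac_differential >= 0, frac_differential <= 1,
              active_fraction >= 0, active_fraction <= 1,
              h33_het_depletion > 0, h31_het_enrichment > 0,
              h3_cen_bump > 0, fold_min > 1, step >= 1, depth > 0,
              track_replicates >= 1)
  })
  structure(cfg, class = "SyntheticConfig")
}

ANTIBODIES <- c("H3.3", "H3.1", "H3", "IgG")

# place features of given lengths into euchromatic segments of one
# chromosome; returns data.table(start, end) or NULL if they cannot fit
.place_in_segments <- function(lengths, segments, gap_mean, min_gap) {
  placed <- vector("list", length(lengths))
  si <- 1L
  pos <- segments$start[si]
  for (i in seq_along(lengths)) {
    repeat {
      gap <- min_gap + round(rexp(1L, 1 / max(1, gap_mean - min_gap)))
      if (pos + gap + lengths[i] <= segments$end[si]) {
        placed[[i]] <- c(pos + gap, pos + gap + lengths[i])
        pos <- pos + gap + lengths[i]
        break
      }
      si <- si + 1L
      if (si > nrow(segments)) return(NULL)
      pos <- segments$start[si]
    }
  }
  m <- do.call(rbind, placed)
  data.table(start = m[, 1], end = m[, 2])
}

#' Generate a synthetic genome, annotation and chromatin states
#'
#' Genes are placed without overlap in the euchromatic arms, separated by
#' inter-annotation gaps; TEs are placed mostly inside the heterochromatin
#' blocks (centromere plus knob); chromatin states paint heterochromatin
#' and TEs CS3, actively-expressed genes CS1, other genes CS2, and the rest
#' CS4 (adjacent same-state runs merged). TFBS-like point sites are placed
#' in the remaining inter-annotation space.
#'
#' @param config a `SyntheticConfig`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `genome` (`GenomeModel`), `features` (genes + TEs),
#'   `states` (merged chromatin-state segments), `sites` (point sites),
#'   and `gene_info` (per-gene table incl. the `active` expression-class
#'   flag used downstream).
#' @export
generate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  with_seed(seed, {
    L <- config$chrom_length
    chrom_names <- sprintf("Chr%d", seq_len(config$n_chromosomes))
    cl <- round(L * config$centromere_fraction)
    cs <- round((L - cl) / 2); ce <- cs + cl
    kl <- config$knob_length
    ks <- max(0, round(L / 4 - kl / 2)); ke <- ks + kl
    if (kl > 0 && ke >= cs) stopf("knob overlaps centromere; reduce knob_length")
    genome <- genome_model(
      data.frame(name = chrom_names, length = L),
      centromeres = data.frame(chrom = chrom_names, start = cs, end = ce),
      heterochromatin = rbind(
        data.frame(chrom = chrom_names, start = cs, end = ce),
        if (kl > 0) data.frame(chrom = chrom_names, start = ks, end = ke)))

    # per-chromosome quotas
    ng_per <- diff(round(seq(0, config$n_genes, length.out =
                               config$n_chromosomes + 1L)))
    n_te_het <- round(config$n_tes * config$te_het_bias)
    n_te_arm <- config$n_tes - n_te_het
    nt_arm_per <- diff(round(seq(0, n_te_arm, length.out =
                                   config$n_chromosomes + 1L)))
    nt_het_per <- diff(round(seq(0, n_te_het, length.out =
                                   config$n_chromosomes + 1L)))

    gene_rows <- list(); te_rows <- list()
    for (ci in seq_along(chrom_names)) {
      cn <- chrom_names[ci]
      eu <- data.table(start = c(0, if (kl > 0) ke else NULL, ce),
                       end = c(if (kl > 0) ks else cs,
                               if (kl > 0) cs else NULL, L))
      ng <- ng_per[ci]; nta <- nt_arm_per[ci]
      lens <- c(pmax(200, round(rlnorm(ng, config$gene_meanlog,
                                       config$gene_sdlog))),
                pmax(100, round(rlnorm(nta, config$te_meanlog,
                                       config$te_sdlog))))
      is_gene <- c(rep(TRUE, ng), rep(FALSE, nta))
      o <- sample.int(length(lens))
      lens <- lens[o]; is_gene <- is_gene[o]
      pl <- .place_in_segments(lens, eu, config$gap_mean, config$min_gap)
      if (is.null(pl))
        stopf("genes cannot fit on %s: reduce n_genes or gene length", cn)
      pl[, `:=`(chrom = cn, gene = is_gene,
                strand = sample(c("+", "-"), .N, replace = TRUE))]
      gene_rows[[ci]] <- pl[gene == TRUE]
      te_rows[[ci]] <- pl[gene == FALSE]

      # heterochromatic TEs inside the het blocks
      nth <- nt_het_per[ci]
      if (nth > 0L) {
        het <- data.table(start = c(if (kl > 0) ks else NULL, cs),
                          end = c(if (kl > 0) ke else NULL, ce))
        tlens <- pmax(100, round(rlnorm(nth, config$te_meanlog,
                                        config$te_sdlog)))
        plh <- .place_in_segments(tlens, het, config$gap_mean / 2,
                                  config$min_gap)
        if (!is.null(plh)) {
          plh[, `:=`(chrom = cn, gene = FALSE,
                     strand = sample(c("+", "-"), .N, replace = TRUE))]
          te_rows[[length(te_rows) + 1L]] <- plh
        }
      }
    }
    genes <- rbindlist(gene_rows)
    tes <- rbindlist(te_rows, fill = TRUE)
    setorder(genes, chrom, start)
    setorder(tes, chrom, start)
    genes[, id := sprintf("gene_%04d", .I)]
    tes[, id := sprintf("TE_%04d", .I)]
    features <- rbind(
      genes[, .(id, chrom, start, end, strand, category = "gene")],
      tes[, .(id, chrom, start, end, strand, category = "TE")])
    setorder(features, chrom, start)
    .validate_features(features)
    .check_features_in_genome(features, genome)

    gene_info <- genes[, .(id, chrom, start, end, strand,
                           length = end - start,
                           active = runif(.N) < config$active_fraction)]

    # chromatin states: het blocks + TEs -> CS3, genes CS1/CS2, rest CS4
    het_dt <- as.data.table(genome$heterochromatin)
    painted <- rbind(
      het_dt[, .(chrom, start, end, state = "CS3")],
      .arm_te_states(tes, het_dt),
      gene_info[, .(chrom, start, end,
                    state = ifelse(active, "CS1", "CS2"))])
    cs4 <- compute_inter_annotation_regions(
      painted[, .(id = sprintf("p%06d", .I), chrom, start, end,
                  strand = ".", category = "other")],
      genome, min_len = 0)
    states <- rbind(painted,
                    cs4[, .(chrom, start, end, state = "CS4")])
    states <- merge_adjacent_state_segments(states)

    # TFBS-like sites in inter-annotation space
    irs <- compute_inter_annotation_regions(features, genome, min_len = 0)
    sites <- .sample_sites(irs, config$n_sites)

    list(genome = genome, features = features, states = states,
         sites = sites, gene_info = gene_info)
  })
}

# states of TEs lying outside heterochromatin blocks (those inside are
# already covered by the CS3 block itself)
.arm_te_states <- function(tes, het_dt) {
  if (nrow(tes) == 0L)
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric(), state = character()))
  inside <- rep(FALSE, nrow(tes))
  for (i in seq_len(nrow(het_dt))) {
    inside <- inside |
      (tes$chrom == het_dt$chrom[i] & tes$start >= het_dt$start[i] &
         tes$end <= het_dt$end[i])
  }
  tes[!inside, .(chrom, start, end, state = "CS3")]
}

.sample_sites <- function(irs, n_sites) {
  if (n_sites == 0L || nrow(irs) == 0L)
    return(data.table(id = character(), chrom = character(), pos = numeric(),
                      strand = character()))
  w <- irs$end - irs$start
  pick <- sample.int(nrow(irs), n_sites, replace = TRUE, prob = w)
  pos <- floor(irs$start[pick] + runif(n_sites) * w[pick])
  out <- data.table(chrom = irs$chrom[pick], pos = pos,
                    strand = sample(c("+", "-"), n_sites, replace = TRUE))
  setorder(out, chrom, pos)
  out[, id := sprintf("site_%05d", .I)]
  setcolorder(out, c("id", "chrom", "pos", "strand"))
  out[]
}

#' Generate a synthetic expression table with ground truth
#'
#' True per-tissue FPKM is drawn log-normal by expression class; a
#' configured fraction of genes receives at least `fold_min`-fold
#' differences between tissues (direction random); replicates are the truth
#' times multiplicative log-normal noise.
#'
#' @param config a `SyntheticConfig`.
#' @param genome_sim output of [generate_genome()].
#' @param seed RNG seed.
#' @return list with `expr` (an `ExpressionTable`) and `truth`
#'   (`data.table`: gene_id, fpkm_dividing, fpkm_nondividing, label in
#'   {up_dividing, up_nondividing, stable}, fold, silent).
#' @export
generate_expression <- function(config, genome_sim, seed = config$seed + 1L) {
  stopifnot(inherits(config, "SyntheticConfig"))
  gi <- genome_sim$gene_info
  n <- nrow(gi)
  with_seed(seed, {
    base <- ifelse(gi$active,
                   rlnorm(n, config$fpkm_meanlog_active,
                          config$fpkm_sdlog_active),
                   rlnorm(n, config$fpkm_meanlog_inactive,
                          config$fpkm_sdlog_inactive))
    silent <- runif(n) < config$frac_silent
    base[silent] <- 0
    diff <- !silent & runif(n) < config$frac_differential
    up_div <- diff & runif(n) < 0.5
    label <- rep("stable", n)
    label[diff & up_div] <- "up_dividing"
    label[diff & !up_div] <- "up_nondividing"
    fold <- rep(1, n)
    fold[diff] <- config$fold_min * exp(rexp(sum(diff), rate = 2))
    fd <- base * ifelse(label == "up_dividing", fold, 1)
    fn <- base * ifelse(label == "up_nondividing", fold, 1)
    truth <- data.table(gene_id = gi$id, fpkm_dividing = fd,
                        fpkm_nondividing = fn, label = label,
                        fold = fold, silent = silent)
    recs <- CJ(tissue = TISSUES, replicate = 1:2, gene_id = gi$id,
               sorted = FALSE)
    tr <- ifelse(recs$tissue == "dividing",
                 truth$fpkm_dividing[match(recs$gene_id, truth$gene_id)],
                 truth$fpkm_nondividing[match(recs$gene_id, truth$gene_id)])
    noise <- rlnorm(nrow(recs), 0, config$replicate_sdlog)
    recs[, fpkm := tr * noise]
    list(expr = expression_table(recs), truth = truth)
  })
}

# expected per-step-bin density for one (tissue, antibody) over one chromosome
.expected_bins <- function(config, genome_sim, truth, tissue, antibody, cn) {
  gm <- genome_sim$genome
  L <- chrom_lengths(gm)[[cn]]
  d <- rep(switch(antibody,
                  "H3.3" = config$h33_baseline,
                  "H3.1" = config$h31_baseline,
                  "H3" = config$h3_baseline,
                  "IgG" = config$igg_level), L)
  if (antibody == "H3.3") {
    gi <- genome_sim$gene_info[chrom == cn]
    fp <- if (tissue == "dividing") truth$fpkm_dividing else
      truth$fpkm_nondividing
    fp <- fp[match(gi$id, truth$gene_id)]
    for (j in seq_len(nrow(gi))) {
      s <- gi$start[j]; e <- gi$end[j]; len <- e - s
      frac <- (seq_len(len) - 0.5) / len        # 5'->3' on the + strand
      if (gi$strand[j] == "-") frac <- rev(frac)
      d[(s + 1):e] <- d[(s + 1):e] + config$h33_slope * log1p(fp[j]) * frac
    }
    het <- as.data.table(gm$heterochromatin)[chrom == cn]
    for (j in seq_len(nrow(het)))
      d[(het$start[j] + 1):het$end[j]] <-
        d[(het$start[j] + 1):het$end[j]] * config$h33_het_depletion
  } else if (antibody == "H3.1") {
    het <- as.data.table(gm$heterochromatin)[chrom == cn]
    for (j in seq_len(nrow(het)))
      d[(het$start[j] + 1):het$end[j]] <-
        d[(het$start[j] + 1):het$end[j]] * config$h31_het_enrichment
  } else if (antibody == "H3") {
    cen <- as.data.table(gm$centromeres)[chrom == cn]
    for (j in seq_len(nrow(cen)))
      d[(cen$start[j] + 1):cen$end[j]] <-
        d[(cen$start[j] + 1):cen$end[j]] * config$h3_cen_bump
  }
  nb <- as.integer(ceiling(L / config$step))
  idx <- rep(seq_len(nb), each = config$step, length.out = L)
  as.vector(rowsum(d, idx) / tabulate(idx, nb))
}

#' Generate synthetic density tracks
#'
#' Deposition is modelled at per-base resolution, averaged onto the step
#' grid, and (optionally) Poisson-sampled: raw counts per bin are
#' `Poisson(expected_density * depth)`. Tracks are unnormalized; the
#' library size is the total count, so [normalize_by_library_size()]
#' restores comparability.
#'
#' @param config a `SyntheticConfig`.
#' @param genome_sim output of [generate_genome()].
#' @param truth truth table from [generate_expression()].
#' @param seed RNG seed.
#' @return nested list `tracks[[tissue]][[antibody]]`: a list of
#'   `track_replicates` raw `SignalTrack`s.
#' @export
generate_tracks <- function(config, genome_sim, truth,
                            seed = config$seed + 2L) {
  stopifnot(inherits(config, "SyntheticConfig"))
  lens <- chrom_lengths(genome_sim$genome)
  with_seed(seed, {
    out <- list()
    for (tissue in TISSUES) {
      out[[tissue]] <- list()
      for (ab in ANTIBODIES) {
        lambda <- lapply(names(lens), function(cn)
          .expected_bins(config, genome_sim, truth, tissue, ab, cn))
        names(lambda) <- names(lens)
        reps <- lapply(seq_len(config$track_replicates), function(r) {
          vals <- lapply(lambda, function(lam) {
            if (config$sampling_noise) as.numeric(rpois(length(lam),
                                                        lam * config$depth))
            else lam * config$depth
          })
          lib <- sum(vapply(vals, sum, numeric(1L)))
          signal_track(vals, step = config$step, chrom_lengths = lens,
                       library_size = max(lib, 1))
        })
        out[[tissue]][[ab]] <- reps
      }
    }
    out
  })
}

#' Simulate a complete dataset
#'
#' Runs [generate_genome()], [generate_expression()] and
#' [generate_tracks()] with seeds derived from `config$seed`.
#'
#' @param config a `SyntheticConfig`.
#' @return list with `config`, `genome`, `features`, `states`, `sites`,
#'   `gene_info`, `expr`, `truth`, `tracks`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  gs <- generate_genome(config, config$seed)
  ex <- generate_expression(config, gs, config$seed + 1L)
  tr <- generate_tracks(config, gs, ex$truth, config$seed + 2L)
  c(list(config = config), gs,
    list(expr = ex$expr, truth = ex$truth, tracks = tr))
}

#' Write a simulated dataset to disk
#'
#' Emits: `genome.tsv`, `annotation.gff3`, `states.bed`, `sites.bed`,
#' `expression.tsv`, `truth.json`, `libraries.tsv` (one row per emitted
#' track with its library size) and one bedGraph per
#' (tissue, antibody, replicate).
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- sim$genome
  genome_dt <- rbind(
    data.table(record = "chromosome", chrom = gm$chromosomes$name,
               start = 0, end = gm$chromosomes$length),
    data.table(record = "centromere", chrom = gm$centromeres$chrom,
               start = gm$centromeres$start, end = gm$centromeres$end),
    data.table(record = "heterochromatin", chrom = gm$heterochromatin$chrom,
               start = gm$heterochromatin$start,
               end = gm$heterochromatin$end))
  fwrite(genome_dt, file.path(dir, "genome.tsv"), sep = "\t", quote = FALSE)

  f <- sim$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1, end = f$end),
    strand = ifelse(f$strand == ".", "*", f$strand))
  S4Vectors::mcols(gr)$type <- ifelse(f$category == "TE",
                                      "transposable_element", f$category)
  S4Vectors::mcols(gr)$ID <- f$id
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")

  write_states_bed(sim$states, file.path(dir, "states.bed"))
  s <- sim$sites
  fwrite(data.table(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE),
                    format(s$pos + 1, scientific = FALSE, trim = TRUE),
                    s$id, 0L, s$strand),
         file.path(dir, "sites.bed"), sep = "\t", col.names = FALSE,
         quote = FALSE)
  edt <- as.data.table(sim$expr)
  edt <- edt[, .(gene_id, tissue, replicate,
                 fpkm = sprintf("%.17g", fpkm))]  # exact float round trip
  fwrite(edt, file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       digits = I(17), dataframe = "columns")

  libs <- list()
  for (tissue in names(sim$tracks)) {
    for (ab in names(sim$tracks[[tissue]])) {
      reps <- sim$tracks[[tissue]][[ab]]
      for (r in seq_along(reps)) {
        fn <- sprintf("track_%s_%s_rep%d.bedgraph", tissue,
                      gsub("\\.", "", ab), r)
        write_track_bedgraph(reps[[r]], file.path(dir, fn))
        libs[[length(libs) + 1L]] <-
          data.table(tissue = tissue, antibody = ab, replicate = r,
                     file = fn, library_size = reps[[r]]$library_size)
      }
    }
  }
  fwrite(rbindlist(libs), file.path(dir, "libraries.tsv"), sep = "\t",
         quote = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @param step track grid step in bp.
#' @return list with `genome`, `features`, `states`, `sites`, `expr`,
#'   `truth`, `tracks` (raw `SignalTrack`s with library sizes attached,
#'   nested as `tracks[[tissue]][[antibody]]` lists).
#' @export
read_dataset <- function(dir, step = 10) {
  gdt <- fread(file.path(dir, "genome.tsv"), sep = "\t")
  genome <- genome_model(
    gdt[record == "chromosome", .(name = chrom, length = end)],
    centromeres = gdt[record == "centromere", .(chrom, start, end)],
    heterochromatin = gdt[record == "heterochromatin", .(chrom, start, end)])
  features <- load_annotation(file.path(dir, "annotation.gff3"), "gff3",
                              genome = genome)
  states <- load_chromatin_states(file.path(dir, "states.bed"))
  sites_raw <- fread(file.path(dir, "sites.bed"), sep = "\t", header = FALSE)
  sites <- data.table(id = sites_raw$V4, chrom = sites_raw$V1,
                      pos = as.numeric(sites_raw$V2), strand = sites_raw$V6)
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  truth <- as.data.table(jsonlite::read_json(file.path(dir, "truth.json"),
                                             simplifyVector = TRUE))
  libs <- fread(file.path(dir, "libraries.tsv"), sep = "\t")
  tracks <- list()
  for (i in seq_len(nrow(libs))) {
    tr <- read_fixed_step_track(file.path(dir, libs$file[i]), genome,
                                step = step,
                                library_size = libs$library_size[i])
    tissue <- libs$tissue[i]; ab <- libs$antibody[i]
    if (is.null(tracks[[tissue]])) tracks[[tissue]] <- list()
    tracks[[tissue]][[ab]] <- c(tracks[[tissue]][[ab]], list(tr))
  }
  list(genome = genome, features = features, states = states, sites = sites,
       expr = expr, truth = truth, tracks = tracks, libraries = libs)
}
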