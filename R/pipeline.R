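# End-to-end orchestration: from a declarative config (or a dataset
# directory) through annotation filtering, track normalization, aggregate
# profiles, distributions, enrichment statistics and developmental
# dynamics, to TSV/JSON outputs and a run manifest.

PIPELINE_STAGES <- c("annotate", "tracks", "profiles", "distributions",
                     "enrichment", "dynamics", "summarize", "report")

#' Default pipeline parameters
#'
#' Every analysis parameter, with the conventional values: 50-bp gene/site
#' bins, 200-kb centromere bins over a 20-Mb span with 1-Mb smoothing,
#' 2-kb site span with 200-bp smoothing, last-kb window 1000 bp, fold
#' threshold 5, ON > 3 / OFF < 1 FPKM, IRs > 150 bp, minimum gene length
#' 1 kb, scatter windows of 10 and 500 genes. Gene-profile smoothing
#' defaults to 500 bp (see the methods vignette on the smoothing window).
#'
#' @return named list of parameters.
#' @export
default_params <- function() {
  list(step = 10, scale = 1e6,
       ir_min_len = 150, min_gene_len = 1000,
       organellar = c("ChrM", "ChrC", "mitochondria", "chloroplast"),
       bin_gene = 50, max_extent = 1500, smooth_gene = 500,
       bin_cen = 2e5, span_cen = 2e7, smooth_cen = 1e6,
       bin_site = 50, span_site = 2000, smooth_site = 200,
       last_kb = 1000, fold = 5, on_thresh = 3, off_thresh = 1,
       window_genes = 10, window_rank = 500)
}

#' Build a run configuration
#'
#' @param data_dir dataset directory (layout of [write_dataset()]).
#' @param out_dir output directory.
#' @param params named list merged over [default_params()].
#' @param groups optional named list (group label -> gene ids) for the
#'   expression group summary.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(data_dir, out_dir, params = list(), groups = NULL) {
  p <- default_params()
  p[names(params)] <- params
  structure(list(data_dir = data_dir, out_dir = out_dir, params = p,
                 groups = groups), class = "RunConfig")
}

#' Load a run configuration from a JSON file
#' @param path JSON file with fields `data_dir`, `out_dir`, optional
#'   `params` and `groups`.
#' @return a `RunConfig`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(j$data_dir, j$out_dir, as.list(j$params),
             if (!is.null(j$groups)) lapply(j$groups, as.character))
}

.stage <- function(name, code) {
  tryCatch(force(code),
           error = function(e)
             stopf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)))
}

#' Run the analysis pipeline
#'
#' Executes, in order: annotation load/filter, track read/normalize/
#' replicate-average, aggregate profiles (centromere, half-gene overall and
#' stratified by expression and length bin, point sites), chromatin-state
#' and feature-class distributions, last-kb enrichment with correlations
#' and windowed scatters, developmental dynamics (fold-change and ON/OFF
#' sets, differential rank scatter), expression summaries, and a run
#' manifest. All prerequisite computation always runs; `stages` only
#' selects which outputs are written, so per-stage subcommands produce
#' byte-identical files to a full run.
#'
#' @param config a `RunConfig` or path to a JSON config.
#' @param stages character subset of
#'   `c("annotate","tracks","profiles","distributions","enrichment",
#'   "dynamics","summarize","report")`; `NULL` means all.
#' @return invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(stages)) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  p <- config$params
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  emit <- function(stage) stage %in% stages
  res <- list()

  ## ---- annotate -----------------------------------------------------
  ann <- .stage("annotate", {
    gdt <- fread(file.path(config$data_dir, "genome.tsv"), sep = "\t")
    genome <- genome_model(
      gdt[record == "chromosome", .(name = chrom, length = end)],
      centromeres = gdt[record == "centromere", .(chrom, start, end)],
      heterochromatin = gdt[record == "heterochromatin",
                            .(chrom, start, end)])
    features <- load_annotation(file.path(config$data_dir,
                                          "annotation.gff3"),
                                "gff3", genome = genome)
    irs <- compute_inter_annotation_regions(features, genome,
                                            min_len = p$ir_min_len)
    states <- merge_adjacent_state_segments(
      load_chromatin_states(file.path(config$data_dir, "states.bed")))
    genes <- features[category == "gene"]
    filt <- filter_genes_for_profiles(genes, features,
                                      min_transcript_len = p$min_gene_len,
                                      organellar_chroms = p$organellar)
    list(genome = genome, features = features, irs = irs, states = states,
         genes = genes, filt = filt)
  })
  if (emit("annotate")) {
    fwrite(ann$features, file.path(out, "features.tsv"), sep = "\t",
           quote = FALSE)
    write_bed6(ann$irs, file.path(out, "irs.bed"), name = "id")
    write_states_bed(ann$states, file.path(out, "states_merged.bed"))
    excl <- ann$filt$excluded
    fwrite(rbind(data.table(id = ann$filt$kept$id, reason = "kept"), excl),
           file.path(out, "gene_filter.tsv"), sep = "\t", quote = FALSE)
  }

  ## ---- expression (input, needed by several stages) ------------------
  expr <- .stage("annotate", {
    ep <- file.path(config$data_dir, "expression.tsv")
    if (!file.exists(ep)) stopf("expression file not found: %s", ep)
    read_expression_tsv(ep)
  })
  everd <- filter_expression(expr)
  means <- expression_means(expr)

  ## ---- tracks --------------------------------------------------------
  trk <- .stage("tracks", {
    libs <- fread(file.path(config$data_dir, "libraries.tsv"), sep = "\t")
    pooled <- list()
    for (tissue in unique(libs$tissue)) {
      pooled[[tissue]] <- list()
      for (ab in unique(libs$antibody[libs$tissue == tissue])) {
        rows <- libs[libs$tissue == tissue & libs$antibody == ab]
        reps <- lapply(seq_len(nrow(rows)), function(i) {
          t <- read_fixed_step_track(
            file.path(config$data_dir, rows$file[i]), ann$genome,
            step = p$step, library_size = rows$library_size[i])
          normalize_by_library_size(t, rows$library_size[i],
                                    scale = p$scale)
        })
        pooled[[tissue]][[ab]] <- average_replicates(reps)
      }
    }
    list(libs = libs, pooled = pooled)
  })
  if (emit("tracks")) {
    summ <- rbindlist(lapply(names(trk$pooled), function(tissue)
      rbindlist(lapply(names(trk$pooled[[tissue]]), function(ab) {
        t <- trk$pooled[[tissue]][[ab]]
        data.table(tissue = tissue, antibody = ab,
                   n_replicates = sum(trk$libs$tissue == tissue &
                                        trk$libs$antibody == ab),
                   mean_signal = mean(unlist(t$values)))
      }))))
    fwrite(summ, file.path(out, "tracks_summary.tsv"), sep = "\t",
           quote = FALSE)
  }

  kept <- ann$filt$kept
  kept_ok <- kept[kept$id %in% everd$gene_id[everd$keep]]
  expressed <- means$gene_id[means$expressed]
  prof_genes <- kept_ok[kept_ok$id %in% expressed]
  flanks <- gene_flanks(prof_genes, ann$irs)
  tissues <- names(trk$pooled)
  abs_avail <- names(trk$pooled[[1L]])

  ## ---- profiles ------------------------------------------------------
  prof <- .stage("profiles", {
    cen <- as.data.table(ann$genome$centromeres)
    cen_anchors <- data.table(chrom = cen$chrom,
                              pos = floor((cen$start + cen$end) / 2),
                              strand = "+")
    cen_profiles <- rbindlist(lapply(tissues, function(tissue)
      rbindlist(lapply(abs_avail, function(ab)
        cbind(tissue = tissue, antibody = ab,
              point_anchored_profile(trk$pooled[[tissue]][[ab]],
                                     cen_anchors, bin = p$bin_cen,
                                     span = p$span_cen,
                                     smooth = p$smooth_cen))))))
    gene_profiles <- rbindlist(lapply(tissues, function(tissue)
      rbindlist(lapply(abs_avail, function(ab)
        cbind(tissue = tissue, antibody = ab, set = "all",
              suppressWarnings(
                halfgene_profile(trk$pooled[[tissue]][[ab]], prof_genes,
                                 flanks, bin = p$bin_gene,
                                 max_extent = p$max_extent,
                                 smooth = p$smooth_gene)))))))
    mm <- means[match(prof_genes$id, means$gene_id)]
    ebins <- as.character(assign_expression_bin(mm$dividing))
    expr_bin_profiles <- rbindlist(lapply(
      levels(assign_expression_bin(1)), function(b) {
        sub <- prof_genes[!is.na(ebins) & ebins == b]
        if (nrow(sub) < 2L) return(NULL)
        rbindlist(lapply(intersect(c("H3.3", "H3.1", "IgG"), abs_avail),
                         function(ab)
          cbind(tissue = "dividing", antibody = ab, set = b,
                suppressWarnings(
                  halfgene_profile(trk$pooled[["dividing"]][[ab]], sub,
                                   flanks, bin = p$bin_gene,
                                   max_extent = p$max_extent,
                                   smooth = p$smooth_gene)))))
      }))
    # length stratification skips the 1-kb exclusion by construction
    lenfilt <- filter_genes_for_profiles(ann$genes, ann$features,
                                         min_transcript_len = 0,
                                         organellar_chroms = p$organellar)
    lgenes <- lenfilt$kept[lenfilt$kept$id %in%
                             everd$gene_id[everd$keep]]
    lbins <- as.character(assign_length_bin(lgenes$end - lgenes$start))
    len_bin_profiles <- rbindlist(lapply(
      levels(assign_length_bin(1)), function(b) {
        sub <- lgenes[lbins == b]
        if (nrow(sub) < 2L) return(NULL)
        rbindlist(lapply(intersect("H3.3", abs_avail), function(ab)
          cbind(tissue = "dividing", antibody = ab, set = b,
                suppressWarnings(
                  halfgene_profile(trk$pooled[["dividing"]][[ab]], sub,
                                   gene_flanks(sub, ann$irs),
                                   bin = p$bin_gene,
                                   max_extent = p$max_extent,
                                   smooth = p$smooth_gene)))))
      }))
    sites_path <- file.path(config$data_dir, "sites.bed")
    site_profiles <- NULL
    if (file.exists(sites_path)) {
      sraw <- fread(sites_path, sep = "\t", header = FALSE)
      sanch <- data.table(chrom = sraw$V1, pos = as.numeric(sraw$V2),
                          strand = sraw$V6)
      site_profiles <- rbindlist(lapply(tissues, function(tissue)
        rbindlist(lapply(abs_avail, function(ab)
          cbind(tissue = tissue, antibody = ab,
                point_anchored_profile(trk$pooled[[tissue]][[ab]], sanch,
                                       bin = p$bin_site,
                                       span = p$span_site,
                                       smooth = p$smooth_site))))))
    }
    list(cen = cen_profiles, genes = gene_profiles,
         ebins = expr_bin_profiles, lbins = len_bin_profiles,
         sites = site_profiles)
  })
  if (emit("profiles")) {
    fwrite(prof$cen, file.path(out, "profile_centromere.tsv"), sep = "\t",
           quote = FALSE)
    fwrite(prof$genes, file.path(out, "profile_genes.tsv"), sep = "\t",
           quote = FALSE)
    fwrite(prof$ebins, file.path(out, "profile_genes_expression_bins.tsv"),
           sep = "\t", quote = FALSE)
    fwrite(prof$lbins, file.path(out, "profile_genes_length_bins.tsv"),
           sep = "\t", quote = FALSE)
    if (!is.null(prof$sites))
      fwrite(prof$sites, file.path(out, "profile_sites.tsv"), sep = "\t",
             quote = FALSE)
  }

  ## ---- distributions -------------------------------------------------
  dists <- .stage("distributions", {
    feats_ir <- rbind(ann$features, ann$irs)
    cs <- rbindlist(lapply(tissues, function(tissue)
      rbindlist(lapply(abs_avail, function(ab)
        cbind(tissue = tissue, antibody = ab,
              distribution_over_regions(trk$pooled[[tissue]][[ab]],
                                        ann$states, by = "state"))))))
    fc <- rbindlist(lapply(tissues, function(tissue)
      rbindlist(lapply(abs_avail, function(ab)
        cbind(tissue = tissue, antibody = ab,
              distribution_over_regions(trk$pooled[[tissue]][[ab]],
                                        feats_ir, by = "category"))))))
    # two-sided Welch test: per antibody, CS1 vs CS3 region means (dividing)
    tests <- lapply(abs_avail, function(ab) {
      t <- trk$pooled[["dividing"]][[ab]]
      s1 <- ann$states[state == "CS1"]
      s3 <- ann$states[state == "CS3"]
      a <- bin_means_multi(t, s1)
      b <- bin_means_multi(t, s3)
      c(list(antibody = ab), welch_t_test(a, b))
    })
    list(cs = cs, features = fc, tests = tests)
  })
  if (emit("distributions")) {
    fwrite(dists$cs, file.path(out, "distributions_cs.tsv"), sep = "\t",
           quote = FALSE)
    fwrite(dists$features, file.path(out, "distributions_features.tsv"),
           sep = "\t", quote = FALSE)
    jsonlite::write_json(dists$tests,
                         file.path(out, "distribution_tests.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## ---- enrichment ----------------------------------------------------
  enr <- .stage("enrichment", {
    eg <- prof_genes[prof_genes$end - prof_genes$start >= p$last_kb]
    tabs <- list()
    for (tissue in tissues) for (ab in abs_avail)
      tabs[[paste(tissue, ab, sep = "|")]] <-
        last_kb_enrichment_table(trk$pooled[[tissue]][[ab]], eg,
                                 k = p$last_kb)
    etab <- rbindlist(lapply(names(tabs), function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
      cbind(tissue = parts[1L], antibody = parts[2L], tabs[[k]])
    }))
    mm <- means[match(eg$id, means$gene_id)]
    cors <- lapply(intersect(c("H3.3", "H3.1", "H3", "IgG"), abs_avail),
                   function(ab) {
      v <- tabs[[paste("dividing", ab, sep = "|")]]$value
      list(antibody = ab, tissue = "dividing",
           rho = spearman_correlation(v, mm$dividing), n = length(v))
    })
    scat <- rbindlist(lapply(intersect(c("H3.3", "H3.1"), abs_avail),
                             function(ab) {
      v <- tabs[[paste("dividing", ab, sep = "|")]]$value
      cbind(antibody = ab,
            windowed_scatter(mm$dividing, v,
                             window = min(p$window_genes, length(v))))
    }))
    list(genes = eg, tabs = tabs, etab = etab, cors = cors, scat = scat)
  })
  if (emit("enrichment")) {
    fwrite(enr$etab, file.path(out, "enrichment.tsv"), sep = "\t",
           quote = FALSE)
    jsonlite::write_json(enr$cors, file.path(out, "correlations.json"),
                         auto_unbox = TRUE, digits = NA)
    fwrite(enr$scat, file.path(out, "scatter_expression_vs_enrichment.tsv"),
           sep = "\t", quote = FALSE)
  }

  ## ---- dynamics ------------------------------------------------------
  dyn <- .stage("dynamics", {
    sets <- select_fold_change_sets(means[means$gene_id %in% kept_ok$id],
                                    fold = p$fold)
    onoff <- select_on_off_sets(means[means$gene_id %in% kept_ok$id],
                                on_thresh = p$on_thresh,
                                off_thresh = p$off_thresh)
    set_profiles <- rbindlist(lapply(names(sets), function(sn) {
      sub <- prof_genes[prof_genes$id %in% sets[[sn]]]
      if (nrow(sub) < 2L) return(NULL)
      rbindlist(lapply(tissues, function(tissue)
        rbindlist(lapply(intersect(c("H3.3", "H3.1"), abs_avail),
                         function(ab)
          cbind(tissue = tissue, antibody = ab, set = sn,
                suppressWarnings(
                  halfgene_profile(trk$pooled[[tissue]][[ab]], sub,
                                   flanks, bin = p$bin_gene,
                                   max_extent = p$max_extent,
                                   smooth = p$smooth_gene)))))))
    }))
    eg <- enr$genes
    mm <- means[match(eg$id, means$gene_id)]
    expr_diff <- setNames(mm$dividing - mm$nondividing, eg$id)
    w <- min(p$window_rank, nrow(eg))
    rank_scat <- rbindlist(lapply(abs_avail, function(ab) {
      ed <- setNames(enr$tabs[[paste("dividing", ab, sep = "|")]]$value -
                       enr$tabs[[paste("nondividing", ab,
                                       sep = "|")]]$value, eg$id)
      cbind(antibody = ab,
            differential_rank_scatter(expr_diff, ed, window = w))
    }))
    list(sets = sets, onoff = onoff, set_profiles = set_profiles,
         rank_scat = rank_scat)
  })
  if (emit("dynamics")) {
    fwrite(dyn$set_profiles, file.path(out, "dynamics_profiles.tsv"),
           sep = "\t", quote = FALSE)
    fwrite(dyn$rank_scat, file.path(out, "dynamics_rank_scatter.tsv"),
           sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(up_in_dividing = dyn$sets$up_in_dividing,
           up_in_nondividing = dyn$sets$up_in_nondividing,
           on_div_off_nondiv = dyn$onoff$on_div_off_nondiv,
           on_nondiv_off_div = dyn$onoff$on_nondiv_off_div),
      file.path(out, "dynamics_sets.json"), digits = NA)
  }

  ## ---- summarize -----------------------------------------------------
  summ <- .stage("summarize", {
    bins <- assign_expression_bin(means$dividing[means$expressed])
    bin_counts <- as.list(table(bins))
    s <- list(
      n_genes_annotation = nrow(ann$genes),
      n_genes_profiled = nrow(prof_genes),
      n_discarded_replicate_filter = sum(!everd$keep),
      n_up_in_dividing = length(dyn$sets$up_in_dividing),
      n_up_in_nondividing = length(dyn$sets$up_in_nondividing),
      expression_bin_counts = bin_counts)
    gs <- if (!is.null(config$groups))
      render_group_summary(summarize_gene_groups(expr, config$groups))
    list(summary = s, groups = gs)
  })
  if (emit("summarize")) {
    jsonlite::write_json(summ$summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(summ$groups))
      fwrite(summ$groups, file.path(out, "group_summary.tsv"), sep = "\t",
             quote = FALSE)
  }

  ## ---- report --------------------------------------------------------
  manifest <- .stage("report", {
    # the hashed config excludes out_dir so that reruns into different
    # directories produce byte-identical manifests
    cfg_min <- list(data_dir = config$data_dir, params = config$params,
                    groups = config$groups)
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg_min, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    md5 <- unname(tools::md5sum(tmp))
    unlink(tmp)
    list(package = "h3profiler",
         version = as.character(utils::packageVersion("h3profiler")),
         config_md5 = md5,
         stages = lapply(intersect(PIPELINE_STAGES, stages), function(s)
           list(stage = s, status = "completed")))
  })
  if (emit("report")) {
    cfg_json <- file.path(out, "config.json")
    jsonlite::write_json(
      list(data_dir = config$data_dir, out_dir = config$out_dir,
           params = config$params, groups = config$groups),
      cfg_json, auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(manifest = manifest, annotate = ann, tracks = trk,
                 profiles = prof, distributions = dists, enrichment = enr,
                 dynamics = dyn, summary = summ))
}

# mean signal of many regions, possibly across chromosomes
#' Mean signal per region across chromosomes
#' @param track `SignalTrack`.
#' @param regions data.frame with chrom, start, end.
#' @return numeric vector of per-region means, in input order.
#' @export
bin_means_multi <- function(track, regions) {
  r <- as.data.table(regions)
  out <- numeric(nrow(r))
  for (cn in unique(r$chrom)) {
    i <- which(r$chrom == cn)
    out[i] <- bin_means(track, cn, r$start[i], r$end[i])
  }
  out
}
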