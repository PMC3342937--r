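# Aggregate (metagene) profiling engine: point-anchored profiles, half-gene
# (TSS/TTS dual-anchored) profiles with flanking inter-annotation regions,
# and centered sliding-mean smoothing.
#
# Offsets are signed bp from the anchor in gene/anchor orientation and label
# the *start* of each bin; minus-strand anchors are coordinate-reversed
# before sampling so all profiles read 5' -> 3'.

#' Centered sliding mean with edge shrink
#'
#' A centered moving average over `window` positions; at the edges the
#' window shrinks to the valid overlap, so output length equals input
#' length. `NA`s are ignored (the window shrinks over them); a window with
#' no non-`NA` values yields `NA`.
#'
#' @param series numeric vector.
#' @param window window size in positions (>= 1; at most twice the series
#'   length).
#' @return numeric vector of the same length.
#' @export
sliding_mean <- function(series, window) {
  n <- length(series)
  if (!is_count(window)) stopf("`window` must be a positive integer")
  if (window > 2L * n) stopf("window larger than twice the series length")
  if (window == 1L) return(as.numeric(series))
  isna <- is.na(series)
  x <- ifelse(isna, 0, as.numeric(series))
  cs <- c(0, cumsum(x))
  cn <- c(0, cumsum(!isna))
  i <- seq_len(n)
  lo <- pmax(1L, i - floor((window - 1L) / 2))
  hi <- pmin(n, i + floor(window / 2))
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# internal: smoothing window in bp -> bins, capped so sliding_mean is valid
.smooth_bins <- function(smooth_bp, bin, series_len) {
  nb <- max(1L, as.integer(round(smooth_bp / bin)))
  min(nb, max(1L, series_len))
}

#' Point-anchored aggregate profile
#'
#' Samples the signal in `bin`-bp windows covering
#' `[pos - span/2, pos + span/2)` around each anchor, flips orientation for
#' minus-strand anchors, averages per bin over anchors, then applies a
#' centered sliding mean of width `smooth` bp. Anchors whose window runs off
#' the chromosome contribute only their fully-contained bins ("clipped
#' anchors contribute partial windows").
#'
#' @param track normalized `SignalTrack`.
#' @param anchors data.frame with columns `chrom`, `pos` (bp), `strand`.
#' @param bin bin width in bp.
#' @param span total profile span in bp (multiple of `bin`).
#' @param smooth smoothing window in bp (default: one bin, i.e. none).
#' @return an `AggregateProfile` `data.table` with columns `segment`
#'   (`"point"`), `offset` (signed bp of bin start from the anchor), `mean`,
#'   `n` (contributing anchors).
#' @export
point_anchored_profile <- function(track, anchors, bin, span, smooth = bin) {
  stopifnot(inherits(track, "SignalTrack"))
  anchors <- as.data.table(anchors)
  if (nrow(anchors) == 0L) stopf("no anchors supplied")
  if (bin > span) stopf("`bin` must not exceed `span`")
  if (span %% bin != 0) stopf("`span` must be a multiple of `bin`")
  offsets <- seq(-span / 2, span / 2 - bin, by = bin)
  nb <- length(offsets)
  na <- nrow(anchors)

  dt <- data.table(
    chrom = rep(anchors$chrom, each = nb),
    strand = rep(anchors$strand, each = nb),
    pos = rep(anchors$pos, each = nb),
    offset = rep(offsets, times = na))
  dt[, start := ifelse(strand == "-", pos - offset - bin, pos + offset)]
  dt[, end := start + bin]
  lens <- track$chrom_lengths
  dt <- dt[start >= 0 & end <= lens[chrom]]
  if (nrow(dt) == 0L) stopf("zero usable anchors: all windows are clipped off")
  dt[, value := bin_means(track, .BY$chrom, start, end), by = chrom]
  prof <- dt[, .(mean = mean(value), n = .N), keyby = offset]
  prof <- merge(data.table(offset = offsets), prof, by = "offset",
                all.x = TRUE, sort = TRUE)
  prof[is.na(n), n := 0L]
  nbs <- .smooth_bins(smooth, bin, nrow(prof))
  prof[, mean := sliding_mean(mean, nbs)]
  prof[, segment := "point"]
  setcolorder(prof, c("segment", "offset", "mean", "n"))
  setattr(prof, "class", c("AggregateProfile", class(prof)))
  setattr(prof, "bin", bin)
  prof[]
}

#' Flanking inter-annotation regions of genes
#'
#' For each gene, finds the IR abutting its 5' and 3' ends (in gene
#' orientation) and reports the flank lengths available for profile
#' sampling. A gene with no abutting IR on a side gets flank length 0.
#'
#' @param genes gene feature table.
#' @param irs IR feature table (e.g. from
#'   [compute_inter_annotation_regions()]).
#' @return `data.table` with columns `id`, `flank5`, `flank3` (bp).
#' @export
gene_flanks <- function(genes, irs) {
  genes <- as.data.table(genes)
  irs <- as.data.table(irs)
  ir_len <- irs$end - irs$start
  up_len <- ir_len[match(paste(genes$chrom, genes$start),
                         paste(irs$chrom, irs$end))]
  dn_len <- ir_len[match(paste(genes$chrom, genes$end),
                         paste(irs$chrom, irs$start))]
  up_len[is.na(up_len)] <- 0
  dn_len[is.na(dn_len)] <- 0
  data.table(id = genes$id,
             flank5 = ifelse(genes$strand == "-", dn_len, up_len),
             flank3 = ifelse(genes$strand == "-", up_len, dn_len))
}

#' Half-gene (TSS/TTS dual-anchored) aggregate profile
#'
#' Each gene contributes four segments sampled 5' to 3' in gene orientation:
#' its 5' flanking IR (offsets negative from the TSS), the 5' half of the
#' gene body anchored at the TSS (offsets >= 0), the 3' half anchored at the
#' TTS (offsets <= -`bin`), and the 3' flanking IR (offsets positive from
#' the TTS). Each half extends to `floor(gene_length / 2)` rounded down to a
#' bin multiple and capped at `max_extent`; per-bin means are taken over the
#' genes that reach that bin, so `n` decreases with |offset| as shorter
#' genes and flanks drop out. Smoothing is applied per segment.
#'
#' @param track normalized `SignalTrack`.
#' @param genes gene feature table (already filtered; genes shorter than
#'   `2 * bin` are skipped with a warning).
#' @param flanks optional `data.table` from [gene_flanks()]; `NULL` means no
#'   flank segments.
#' @param bin bin width in bp (default 50).
#' @param max_extent maximum extent of each segment in bp (multiple of
#'   `bin`).
#' @param smooth smoothing window in bp.
#' @return an `AggregateProfile` `data.table` with columns `segment` (one of
#'   `"5flank"`, `"5half"`, `"3half"`, `"3flank"`), `offset`, `mean`, `n`.
#' @export
halfgene_profile <- function(track, genes, flanks = NULL, bin = 50,
                             max_extent = 1500, smooth = 500) {
  stopifnot(inherits(track, "SignalTrack"))
  genes <- as.data.table(genes)
  if (nrow(genes) == 0L) stopf("empty gene set")
  if (max_extent %% bin != 0) stopf("`max_extent` must be a multiple of `bin`")
  short <- (genes$end - genes$start) < 2 * bin
  if (any(short)) {
    warnf("skipping %d gene(s) shorter than 2 * bin", sum(short))
    genes <- genes[!short]
    if (nrow(genes) == 0L) stopf("empty gene set after skipping short genes")
  }
  if (is.null(flanks))
    flanks <- data.table(id = genes$id, flank5 = 0, flank3 = 0)
  g <- merge(genes, flanks, by = "id", all.x = TRUE, sort = FALSE)
  g[is.na(flank5), flank5 := 0]
  g[is.na(flank3), flank3 := 0]
  maxb <- max_extent %/% bin
  g[, `:=`(
    tss = ifelse(strand == "-", end, start),
    tts = ifelse(strand == "-", start, end),
    nb_half = pmin((end - start) %/% 2 %/% bin, maxb),
    nb_f5 = pmin(flank5 %/% bin, maxb),
    nb_f3 = pmin(flank3 %/% bin, maxb))]

  # expand per-gene bins for one segment; `off` are oriented bin starts
  expand <- function(nbins, anchor, seg, side) {
    idx <- rep.int(seq_len(nrow(g)), nbins)
    off <- unlist(lapply(nbins, function(k) {
      if (k == 0L) return(numeric(0))
      if (side == "plus") seq(0, by = bin, length.out = k)
      else seq(-k * bin, by = bin, length.out = k)
    }), use.names = FALSE)
    if (!length(idx)) return(NULL)
    data.table(chrom = g$chrom[idx], strand = g$strand[idx],
               anchor = anchor[idx], offset = off, segment = seg)
  }
  parts <- rbindlist(list(
    expand(g$nb_f5, g$tss, "5flank", "minus"),
    expand(g$nb_half, g$tss, "5half", "plus"),
    expand(g$nb_half, g$tts, "3half", "minus"),
    expand(g$nb_f3, g$tts, "3flank", "plus")))
  if (is.null(parts) || nrow(parts) == 0L)
    stopf("no sampleable bins: genes and flanks shorter than one bin")

  # oriented bin [offset, offset + bin) -> genomic coordinates
  parts[, start := ifelse(strand == "-", anchor - offset - bin,
                          anchor + offset)]
  parts[, end := start + bin]
  lens <- track$chrom_lengths
  parts <- parts[start >= 0 & end <= lens[chrom]]
  parts[, value := bin_means(track, .BY$chrom, start, end), by = chrom]

  seg_levels <- c("5flank", "5half", "3half", "3flank")
  prof <- parts[, .(mean = mean(value), n = .N),
                keyby = .(segment, offset)]
  prof[, seg_ord := match(segment, seg_levels)]
  setorder(prof, seg_ord, offset)
  prof[, mean := sliding_mean(mean, .smooth_bins(smooth, bin, .N)),
       by = segment]
  prof[, seg_ord := NULL]
  setcolorder(prof, c("segment", "offset", "mean", "n"))
  setattr(prof, "class", c("AggregateProfile", class(prof)))
  setattr(prof, "bin", bin)
  prof[]
}

#' Write an aggregate profile as TSV
#' @param profile `AggregateProfile`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_profile_tsv <- function(profile, path) {
  fwrite(as.data.table(profile), path, sep = "\t", quote = FALSE)
  invisible(path)
}
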