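# Independent brute-force oracles. These deliberately use naive per-base /
# linear-scan computation and never call the package's optimized paths.

# per-base expansion of a step track on one chromosome
oracle_per_base <- function(track, chrom) {
  len <- track$chrom_lengths[[chrom]]
  rep(track$values[[chrom]], each = track$step)[seq_len(len)]
}

oracle_mean_signal <- function(track, chrom, start, end) {
  pb <- oracle_per_base(track, chrom)
  mean(pb[(start + 1):end])
}

# complement of the union of features on [0, len), as a data.frame
oracle_complement <- function(starts, ends, len) {
  covered <- logical(len)
  for (i in seq_along(starts))
    covered[(starts[i] + 1):ends[i]] <- TRUE
  r <- rle(covered)
  e <- cumsum(r$lengths)
  s <- c(0, head(e, -1))
  data.frame(start = s[!r$values], end = e[!r$values])
}

# linear scan merge of sorted state segments
oracle_merge_states <- function(seg) {
  seg <- seg[order(seg$chrom, seg$start), ]
  out <- seg[0, ]
  for (i in seq_len(nrow(seg))) {
    if (nrow(out) > 0 &&
        out$chrom[nrow(out)] == seg$chrom[i] &&
        out$state[nrow(out)] == seg$state[i] &&
        out$end[nrow(out)] == seg$start[i]) {
      out$end[nrow(out)] <- seg$end[i]
    } else {
      out <- rbind(out, seg[i, ])
    }
  }
  out
}

oracle_sliding_mean <- function(x, w) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    lo <- max(1, i - floor((w - 1) / 2))
    hi <- min(n, i + floor(w / 2))
    mean(x[lo:hi], na.rm = TRUE)
  })
}

# per-anchor, per-base point profile; bins fully inside the chromosome only
oracle_point_profile <- function(track, anchors, bin, span) {
  offsets <- seq(-span / 2, span / 2 - bin, by = bin)
  pbs <- lapply(setNames(nm = unique(anchors$chrom)), function(cn)
    oracle_per_base(track, cn))
  acc <- matrix(NA_real_, nrow = nrow(anchors), ncol = length(offsets))
  for (a in seq_len(nrow(anchors))) {
    cn <- anchors$chrom[a]; pos <- anchors$pos[a]
    len <- track$chrom_lengths[[cn]]
    pb <- pbs[[cn]]
    for (j in seq_along(offsets)) {
      o <- offsets[j]
      s <- if (anchors$strand[a] == "-") pos - o - bin else pos + o
      e <- s + bin
      if (s >= 0 && e <= len)
        acc[a, j] <- mean(pb[(s + 1):e])
    }
  }
  data.frame(offset = offsets,
             mean = apply(acc, 2, function(v)
               if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)),
             n = apply(acc, 2, function(v) sum(!is.na(v))))
}

# per-gene, per-base half-gene profile (no smoothing, no flanks unless given)
oracle_halfgene_profile <- function(track, genes, flanks = NULL, bin,
                                    max_extent) {
  maxb <- max_extent %/% bin
  pbs <- lapply(setNames(nm = unique(genes$chrom)), function(cn)
    oracle_per_base(track, cn))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start
    if (len < 2 * bin) next
    nbh <- min((len %/% 2) %/% bin, maxb)
    minus <- g$strand == "-"
    tss <- if (minus) g$end else g$start
    tts <- if (minus) g$start else g$end
    pb <- pbs[[g$chrom]]
    samp <- function(anchor, off) {
      s <- if (minus) anchor - off - bin else anchor + off
      mean(pb[(s + 1):(s + bin)])
    }
    f5 <- f3 <- 0
    if (!is.null(flanks)) {
      fr <- flanks[flanks$id == g$id, ]
      if (nrow(fr) == 1) { f5 <- min(fr$flank5 %/% bin, maxb)
                           f3 <- min(fr$flank3 %/% bin, maxb) }
    }
    for (j in seq_len(f5))
      rows[[length(rows) + 1]] <- data.frame(
        segment = "5flank", offset = -j * bin, v = samp(tss, -j * bin))
    for (j in seq_len(nbh)) {
      rows[[length(rows) + 1]] <- data.frame(
        segment = "5half", offset = (j - 1) * bin, v = samp(tss, (j - 1) * bin))
      rows[[length(rows) + 1]] <- data.frame(
        segment = "3half", offset = -j * bin, v = samp(tts, -j * bin))
    }
    for (j in seq_len(f3))
      rows[[length(rows) + 1]] <- data.frame(
        segment = "3flank", offset = (j - 1) * bin, v = samp(tts, (j - 1) * bin))
  }
  d <- do.call(rbind, rows)
  agg <- aggregate(v ~ segment + offset, data = d, FUN = mean)
  cnt <- aggregate(v ~ segment + offset, data = d, FUN = length)
  names(agg)[3] <- "mean"; names(cnt)[3] <- "n"
  m <- merge(agg, cnt)
  m[order(match(m$segment, c("5flank", "5half", "3half", "3flank")),
          m$offset), ]
}

# tie-averaged ranks computed from first principles
oracle_avg_rank <- function(x) {
  sapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2)
}

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x); ry <- oracle_avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_quantile_type7 <- function(v, p) {
  v <- sort(v); n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
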