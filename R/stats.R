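# Enrichment statistics: last-1-kb 3' enrichment, tie-averaged Spearman
# rank correlation, sliding-window scatter series, per-class signal
# distributions, and the Welch two-sided t-test.

#' Mean signal over the last k bp of a gene (3' end, gene orientation)
#'
#' The signature statistic correlated with expression: the coverage-weighted
#' mean of the normalized signal over the `k` bp immediately 5' of the TTS.
#' For minus-strand genes this is the first `k` bp of the interval.
#'
#' @param track normalized `SignalTrack`.
#' @param gene one-row gene feature (or anything with `chrom`, `start`,
#'   `end`, `strand`).
#' @param k window in bp (default 1000); genes shorter than `k` are an
#'   error (they are excluded upstream).
#' @return scalar mean signal.
#' @export
last_kb_enrichment <- function(track, gene, k = 1000) {
  gene <- as.data.table(gene)
  if (nrow(gene) != 1L) stopf("`gene` must be a single feature")
  if (gene$end - gene$start < k)
    stopf("gene %s is shorter than k = %d bp", gene$id %||% "?", k)
  if (gene$strand == "-") {
    mean_signal(track, gene$chrom, gene$start, gene$start + k)
  } else {
    mean_signal(track, gene$chrom, gene$end - k, gene$end)
  }
}

#' Last-k-bp enrichment for a whole gene table (vectorized)
#'
#' @param track normalized `SignalTrack`.
#' @param genes gene feature table; all genes must be at least `k` bp.
#' @param k window in bp.
#' @return `data.table` with columns `gene_id`, `value`.
#' @export
last_kb_enrichment_table <- function(track, genes, k = 1000) {
  g <- copy(as.data.table(genes))
  if (any(g$end - g$start < k))
    stopf("all genes must be at least k = %d bp for last-kb enrichment", k)
  g[, `:=`(ws = ifelse(strand == "-", start, end - k))]
  g[, value := bin_means(track, .BY$chrom, ws, ws + k), by = chrom]
  g[, .(gene_id = id, value)]
}

#' Tie-averaged Spearman rank correlation
#'
#' Pearson correlation of ranks, with average ranks assigned to ties.
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant after
#'   ranking.
#' @return rho in [-1, 1].
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("inputs must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0)
    stopf("correlation undefined for a constant vector")
  cor(rx, ry)
}

#' Sliding-window scatter series
#'
#' Sorts the (x, y) pairs by `x` ascending (ties keep stable input order)
#' and emits centered sliding means of both coordinates over `window`
#' consecutive observations, one output per input position with edge
#' shrink.
#'
#' @param x,y numeric vectors of equal length.
#' @param window window in observations (default 10, <= n).
#' @return `data.table` with columns `xbar`, `ybar`.
#' @export
windowed_scatter <- function(x, y, window = 10) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (!is_count(window)) stopf("`window` must be a positive integer")
  if (window > length(x)) stopf("`window` must not exceed n")
  o <- order(x)  # radix sort: stable for ties
  data.table(xbar = sliding_mean(x[o], window),
             ybar = sliding_mean(y[o], window))
}

#' Differential rank scatter series
#'
#' Converts per-gene expression and enrichment differences (dividing minus
#' non-dividing) to tie-averaged ranks, orders genes by the expression-
#' difference rank, and emits centered sliding means of both rank series
#' over `window` genes.
#'
#' @param expr_diff,enr_diff named numeric vectors over the same gene
#'   universe.
#' @param window window in genes (default 500, <= n).
#' @return `data.table` with columns `gene_id`, `expr_rank`, `enr_rank`
#'   (smoothed ranks, in expression-difference order).
#' @export
differential_rank_scatter <- function(expr_diff, enr_diff, window = 500) {
  if (is.null(names(expr_diff)) || is.null(names(enr_diff)) ||
      !setequal(names(expr_diff), names(enr_diff)))
    stopf("expr_diff and enr_diff must be named over the same gene set")
  enr_diff <- enr_diff[names(expr_diff)]
  n <- length(expr_diff)
  if (!is_count(window) || window > n)
    stopf("`window` must be a positive integer <= n")
  rx <- rank(expr_diff, ties.method = "average")
  ry <- rank(enr_diff, ties.method = "average")
  o <- order(rx)
  data.table(gene_id = names(expr_diff)[o],
             expr_rank = sliding_mean(rx[o], window),
             enr_rank = sliding_mean(ry[o], window))
}

#' Signal distribution over region classes
#'
#' Computes the coverage-weighted mean signal of each region, then a
#' five-number summary (min, Q1, median, Q3, max; quartiles by linear
#' interpolation, quantile type 7) per class.
#'
#' @param track normalized `SignalTrack`.
#' @param regions data.frame of intervals with a class column.
#' @param by name of the class column (e.g. `"category"` or `"state"`).
#' @param classes optional class labels expected; classes with no region
#'   are omitted with a warning.
#' @return `data.table` with columns `class`, `min`, `q1`, `median`, `q3`,
#'   `max`, `n`.
#' @export
distribution_over_regions <- function(track, regions, by = "category",
                                      classes = NULL) {
  r <- copy(as.data.table(regions))
  if (!by %in% names(r)) stopf("no column '%s' in regions", by)
  if (nrow(r) == 0L) stopf("no regions supplied")
  r[, value := bin_means(track, .BY$chrom, start, end), by = chrom]
  lab <- as.character(r[[by]])
  if (!is.null(classes)) {
    empty <- setdiff(classes, unique(lab))
    if (length(empty))
      warnf("omitting empty class(es): %s", paste(empty, collapse = ", "))
  }
  out <- r[, {
    q <- quantile(value, probs = c(0, .25, .5, .75, 1), type = 7,
                  names = FALSE)
    .(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5], n = .N)
  }, by = .(class = lab)]
  setorder(out, class)
  out[]
}

#' Welch two-sample t-test (two-sided)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param a,b numeric samples, each of size >= 2, with positive variance in
#'   at least one.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("each sample needs n >= 2")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stopf("degenerate samples: both variances are 0")
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}
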