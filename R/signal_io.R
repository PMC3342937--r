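# Fixed-step density tracks: reading WIG/bedGraph onto a step grid,
# per-million library normalization, and coverage-weighted interval means.
# Track values are per-base densities held constant within each step bin;
# positions absent from a file are 0 (density semantics), not NA.

#' Construct a signal track
#'
#' @param values named list of per-chromosome numeric vectors, one value per
#'   step window (`length == ceiling(chrom_length / step)`).
#' @param step bin width in bp.
#' @param chrom_lengths named numeric vector of chromosome lengths; defaults
#'   to `step * length(values[[i]])` per chromosome.
#' @param library_size total mapped reads of the underlying library.
#' @param normalized whether values are already library-size normalized.
#' @return an object of class `SignalTrack`.
#' @export
signal_track <- function(values, step = 10, chrom_lengths = NULL,
                         library_size = NA_real_, normalized = FALSE) {
  if (!is.list(values) || is.null(names(values)) || !all(nzchar(names(values))))
    stopf("`values` must be a named list of numeric vectors")
  if (!is_count(step)) stopf("`step` must be a positive integer")
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(!is.finite(v)) || any(v < 0),
                 logical(1L))))
    stopf("track values must be finite and >= 0")
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(values, function(v) length(v) * step, numeric(1L))
  chrom_lengths <- chrom_lengths[names(values)]
  nb <- ceiling(chrom_lengths / step)
  if (any(vapply(values, length, integer(1L)) != nb))
    stopf("vector lengths must equal ceiling(chrom_length / step)")
  structure(list(values = values, step = step,
                 chrom_lengths = chrom_lengths,
                 library_size = as.numeric(library_size),
                 normalized = isTRUE(normalized)),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: %d chromosome(s), step %d bp, %s\n",
              length(x$values), x$step,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Read a fixed-step density track from WIG or bedGraph
#'
#' fixedStep/variableStep WIG and bedGraph are parsed with `rtracklayer` and
#' resampled onto the `step` grid by coverage-weighted mean; positions absent
#' from the file hold 0.
#'
#' @param path track file.
#' @param genome `GenomeModel` giving chromosome names and lengths.
#' @param step grid step in bp (default 10).
#' @param format `"auto"` (by extension), `"wig"` or `"bedGraph"`.
#' @param library_size optional mapped-read count to attach.
#' @return a raw (unnormalized) `SignalTrack`.
#' @export
read_fixed_step_track <- function(path, genome, step = 10,
                                  format = c("auto", "wig", "bedGraph"),
                                  library_size = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("track file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, wig = "wig", bedgraph = "bedGraph", bg = "bedGraph",
                     stopf("cannot infer track format from extension '%s'", ext))
  }
  lens <- chrom_lengths(genome)
  empty <- !any(nzchar(sub("#.*", "", readLines(path, warn = FALSE))))
  if (empty) {
    vals <- lapply(lens, function(l) numeric(ceiling(l / step)))
    return(signal_track(vals, step = step, chrom_lengths = lens,
                        library_size = library_size))
  }
  gr <- rtracklayer::import(path, format = format)
  used <- unique(as.character(GenomicRanges::seqnames(gr)))
  unknown <- setdiff(used, names(lens))
  if (length(unknown))
    stopf("track references unknown chromosomes: %s",
          paste(unknown, collapse = ", "))
  score <- as.numeric(gr$score)
  if (any(!is.finite(score)) || any(score < 0))
    stopf("validation error: negative or non-finite track values")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  vals <- lapply(names(lens), function(cn) {
    len <- lens[[cn]]
    nb <- as.integer(ceiling(len / step))
    i <- which(chroms == cn)
    if (!length(i)) return(numeric(nb))
    if (any(ends[i] > len))
      stopf("track interval beyond end of chromosome %s", cn)
    cov <- IRanges::coverage(IRanges::IRanges(starts[i], ends[i]),
                             weight = score[i], width = as.integer(len))
    bs <- seq(1L, by = step, length.out = nb)
    bins <- IRanges::IRanges(start = bs,
                             width = pmin(step, as.integer(len) - bs + 1L))
    as.numeric(IRanges::viewMeans(IRanges::Views(cov, bins)))
  })
  names(vals) <- names(lens)
  signal_track(vals, step = step, chrom_lengths = lens,
               library_size = library_size)
}

#' Normalize a track by library size
#'
#' Multiplies every value by `scale / mapped_reads` (per-million by default),
#' making density tracks from libraries of different depth directly
#' comparable. Normalizing twice is an error.
#'
#' @param track `SignalTrack`.
#' @param mapped_reads total mapped reads (> 0); defaults to the track's
#'   recorded `library_size`.
#' @param scale scale constant (default 1e6, i.e. per million mapped reads).
#' @return normalized `SignalTrack`.
#' @export
normalize_by_library_size <- function(track, mapped_reads = track$library_size,
                                      scale = 1e6) {
  stopifnot(inherits(track, "SignalTrack"))
  if (track$normalized) stopf("track is already normalized")
  if (!is.numeric(mapped_reads) || length(mapped_reads) != 1L ||
      is.na(mapped_reads) || mapped_reads <= 0)
    stopf("`mapped_reads` must be a single positive number")
  f <- scale / mapped_reads
  track$values <- lapply(track$values, function(v) v * f)
  track$library_size <- as.numeric(mapped_reads)
  track$normalized <- TRUE
  track
}

# cumulative integral of per-base density at arbitrary bp coordinates;
# vectorized over x. `vals` are per-base densities constant on step bins.
.track_integral <- function(vals, step, x) {
  cs <- c(0, cumsum(vals)) * step
  k <- pmin(floor(x / step), length(vals) - 1L)
  cs[k + 1L] + vals[k + 1L] * (x - k * step)
}

#' Coverage-weighted mean signal over intervals (vectorized)
#'
#' @param track `SignalTrack`.
#' @param chrom chromosome name (scalar).
#' @param starts,ends 0-based half-open interval coordinates (vectors of
#'   equal length). Partial step bins are weighted by overlap length.
#' @return numeric vector of means.
#' @export
bin_means <- function(track, chrom, starts, ends) {
  stopifnot(inherits(track, "SignalTrack"))
  v <- track$values[[chrom]]
  if (is.null(v)) stopf("unknown chromosome '%s'", chrom)
  len <- track$chrom_lengths[[chrom]]
  if (length(starts) != length(ends)) stopf("starts/ends length mismatch")
  if (any(starts < 0 | ends > len | ends <= starts))
    stopf("interval out of range on %s", chrom)
  (.track_integral(v, track$step, ends) -
     .track_integral(v, track$step, starts)) / (ends - starts)
}

#' Mean signal over one interval
#'
#' @inheritParams bin_means
#' @param start,end 0-based half-open interval.
#' @return scalar mean.
#' @export
mean_signal <- function(track, chrom, start, end) {
  bin_means(track, chrom, start, end)
}

#' Element-wise mean of replicate tracks
#'
#' @param tracks list of `SignalTrack`s on identical grids, all normalized.
#' @return a `SignalTrack`; `library_size` is the mean of the inputs'.
#' @export
average_replicates <- function(tracks) {
  if (!length(tracks)) stopf("need at least one track")
  stopifnot(all(vapply(tracks, inherits, logical(1L), "SignalTrack")))
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (t$step != ref$step ||
        !identical(names(t$values), names(ref$values)) ||
        !isTRUE(all.equal(t$chrom_lengths, ref$chrom_lengths)))
      stopf("tracks are on mismatched grids")
  }
  if (!all(vapply(tracks, function(t) t$normalized, logical(1L))))
    stopf("all tracks must be normalized before averaging")
  vals <- setNames(lapply(names(ref$values), function(cn) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[cn]])) / length(tracks)
  }), names(ref$values))
  signal_track(vals, step = ref$step, chrom_lengths = ref$chrom_lengths,
               library_size = mean(vapply(tracks, function(t) t$library_size,
                                          numeric(1L))),
               normalized = TRUE)
}

#' Write a track as bedGraph
#'
#' Runs of equal values are collapsed; zero runs are omitted (missing = 0 on
#' re-read). Values are written with full double precision so a write/read
#' round trip is exact.
#'
#' @param track `SignalTrack`.
#' @param path output path (use a `.bedgraph` extension for auto-detection).
#' @return invisibly, the path.
#' @export
write_track_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "SignalTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    len <- track$chrom_lengths[[cn]]
    r <- rle(v)
    ends <- pmin(cumsum(r$lengths) * track$step, len)
    starts <- c(0, head(ends, -1L))
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%s\t%s\t%.17g", cn,
                       format(starts[keep], scientific = FALSE, trim = TRUE),
                       format(ends[keep], scientific = FALSE, trim = TRUE),
                       r$values[keep]), con)
  }
  invisible(path)
}

#' Write a track as fixedStep WIG
#'
#' All step values are written (including zeros) with full double precision.
#'
#' @inheritParams write_track_bedgraph
#' @return invisibly, the path.
#' @export
write_track_wig <- function(track, path) {
  stopifnot(inherits(track, "SignalTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  step <- track$step
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    len <- track$chrom_lengths[[cn]]
    nfull <- as.integer(len %/% step)
    rem <- len - nfull * step
    if (nfull > 0L) {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                         cn, step, step), con)
      writeLines(sprintf("%.17g", v[seq_len(nfull)]), con)
    }
    if (rem > 0) {
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         cn, nfull * step + 1L, step, as.integer(rem)), con)
      writeLines(sprintf("%.17g", v[nfull + 1L]), con)
    }
  }
  invisible(path)
}
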