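# Annotation handling: feature tables, inter-annotation regions (IRs),
# chromatin-state segment merging, and the gene-exclusion filters applied
# before metagene profiling.

#' Construct a feature table
#'
#' Features are stranded genomic intervals with a category. Coordinates are
#' 0-based half-open. IR (inter-annotation region) features are unstranded by
#' definition.
#'
#' @param id character ids (unique).
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param category one of `"gene"`, `"TE"`, `"other"`, `"IR"`.
#' @return a `data.table` with one row per feature.
#' @export
feature_table <- function(id, chrom, start, end, strand = ".",
                          category = "gene") {
  dt <- data.table(id = as.character(id), chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   category = as.character(category))
  .validate_features(dt)
  dt[]
}

.validate_features <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(!dt$strand %in% c("+", "-", ".")))
    stopf("strand must be one of '+', '-', '.'")
  if (any(!dt$category %in% c("gene", "TE", "other", "IR")))
    stopf("category must be one of 'gene', 'TE', 'other', 'IR'")
  if (any(dt$start < 0 | dt$end <= dt$start))
    stopf("features must satisfy 0 <= start < end")
  if (any(dt$category == "IR" & dt$strand != "."))
    stopf("IR features must be unstranded ('.')")
  invisible(dt)
}

#' Default mapping from annotation types to feature categories
#'
#' Maps GFF3 `type` values (or BED name tokens) onto the package's feature
#' categories. Anything not in the map becomes `"other"`.
#' @return named character vector.
#' @export
default_category_map <- function() {
  c(gene = "gene",
    protein_coding_gene = "gene",
    mRNA = "gene",
    transposable_element = "TE",
    transposable_element_gene = "TE",
    transposon = "TE",
    pseudogene = "TE")
}

# quick structural scan so that malformed lines are reported with their
# line number (rtracklayer's errors do not carry one)
.prescan_lines <- function(path, dialect) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (dialect == "gff3") {
      if (startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 9L)
        stopf("parse error at line %d of %s: expected 9 tab-separated fields, got %d",
              i, path, length(f))
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (is.na(s) || is.na(e))
        stopf("parse error at line %d of %s: non-numeric coordinates", i, path)
      if (e < s)
        stopf("validation error at line %d of %s: end < start", i, path)
    } else {
      if (startsWith(ln, "track") || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L)
        stopf("parse error at line %d of %s: expected >= 3 tab-separated fields",
              i, path)
      s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || is.na(e))
        stopf("parse error at line %d of %s: non-numeric coordinates", i, path)
      if (e <= s)
        stopf("validation error at line %d of %s: end <= start", i, path)
      if (length(f) >= 6L && !f[6] %in% c("+", "-", "."))
        stopf("parse error at line %d of %s: bad strand '%s'", i, path, f[6])
    }
  }
  lines
}

#' Load a genomic annotation file
#'
#' Reads GFF3 (1-based inclusive, converted to the internal 0-based half-open
#' frame) or BED (native half-open) and assigns feature categories through a
#' configurable mapping of the GFF3 `type` (or BED `name`) field.
#'
#' @param path file path.
#' @param dialect `"gff3"` or `"bed"`.
#' @param category_map named character vector mapping type/name values to
#'   categories; see [default_category_map()].
#' @param default_category category for unmapped types.
#' @param genome optional `GenomeModel` to validate coordinates against.
#' @return a feature `data.table` (see [feature_table()]).
#' @export
load_annotation <- function(path, dialect = c("gff3", "bed"),
                            category_map = default_category_map(),
                            default_category = "other", genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- .prescan_lines(path, dialect)
  has_data <- if (dialect == "gff3")
    any(nzchar(lines) & !startsWith(lines, "#"))
  else
    any(nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#"))
  if (!has_data)
    return(feature_table(character(), character(), numeric(), numeric(),
                         character(), character()))

  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    ids <- as.character(ids)
    ids[is.na(ids) | !nzchar(ids)] <-
      sprintf("feat_%05d", which(is.na(ids) | !nzchar(ids)))
    cat_key <- type
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- gr$name
    if (is.null(ids)) ids <- sprintf("feat_%05d", seq_along(gr))
    ids <- as.character(ids)
    cat_key <- ids
  }
  category <- unname(category_map[cat_key])
  category[is.na(category)] <- default_category
  dt <- data.table(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    category = category)
  dt[strand == "*", strand := "."]
  dt[category == "IR", strand := "."]
  .validate_features(dt)
  if (!is.null(genome)) .check_features_in_genome(dt, genome)
  dt[]
}

#' Compute inter-annotation regions (IRs)
#'
#' The per-chromosome complement of the union of all annotated features,
#' retaining only intervals strictly longer than `min_len` (the conventional
#' cutoff keeps IRs > 150 bp).
#'
#' @param features feature table (any categories; IR rows are ignored).
#' @param genome `GenomeModel`.
#' @param min_len minimum IR length in bp (strictly greater than).
#' @return feature table of category `"IR"`, sorted by (chrom, start).
#' @export
compute_inter_annotation_regions <- function(features, genome,
                                             min_len = 150) {
  feats <- as.data.table(features)[category != "IR"]
  .check_features_in_genome(feats, genome)
  lens <- chrom_lengths(genome)
  out <- lapply(names(lens), function(cn) {
    len <- lens[[cn]]
    f <- feats[chrom == cn]
    ir <- IRanges::gaps(
      IRanges::reduce(IRanges::IRanges(start = f$start + 1, end = f$end)),
      start = 1L, end = as.integer(len))
    data.table(chrom = cn,
               start = as.numeric(IRanges::start(ir) - 1),
               end = as.numeric(IRanges::end(ir)))
  })
  out <- rbindlist(out)
  out <- out[end - start > min_len]
  setorder(out, chrom, start)
  if (nrow(out) == 0L)
    return(feature_table(character(), character(), numeric(), numeric(),
                         character(), character()))
  out[, `:=`(id = sprintf("IR_%05d", .I), strand = ".", category = "IR")]
  setcolorder(out, c("id", "chrom", "start", "end", "strand", "category"))
  out[]
}

#' Merge abutting chromatin-state segments of equal state
#'
#' Maximal runs of abutting (`end == next start`) same-state segments on the
#' same chromosome are collapsed into a single segment. Overlapping segments
#' on the same chromosome are a validation error.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`, `state`
#'   (one of CS1..CS4).
#' @return merged `data.table`, sorted by (chrom, start).
#' @export
merge_adjacent_state_segments <- function(segments) {
  seg <- as.data.table(segments)[, .(chrom = as.character(chrom),
                                     start = as.numeric(start),
                                     end = as.numeric(end),
                                     state = as.character(state))]
  if (any(!seg$state %in% c("CS1", "CS2", "CS3", "CS4")))
    stopf("state must be one of CS1, CS2, CS3, CS4")
  if (any(seg$start < 0 | seg$end <= seg$start))
    stopf("segments must satisfy 0 <= start < end")
  setorder(seg, chrom, start)
  if (nrow(seg) > 1L) {
    same <- seg$chrom[-1L] == seg$chrom[-nrow(seg)]
    if (any(same & seg$start[-1L] < seg$end[-nrow(seg)]))
      stopf("validation error: overlapping segments on the same chromosome")
  }
  if (nrow(seg) == 0L) return(seg[])
  newrun <- c(TRUE, !(seg$chrom[-1L] == seg$chrom[-nrow(seg)] &
                      seg$state[-1L] == seg$state[-nrow(seg)] &
                      seg$start[-1L] == seg$end[-nrow(seg)]))
  seg[, grp := cumsum(newrun)]
  out <- seg[, .(chrom = chrom[1L], start = start[1L], end = end[.N],
                 state = state[1L]), by = grp][, grp := NULL]
  out[]
}

#' Filter genes for metagene profiling
#'
#' Applies the standard exclusions before aggregate gene profiles are built:
#' organellar genes (by chromosome name), genes whose interval intersects any
#' other non-IR annotation (>= 1 bp, strand-blind), and genes shorter than
#' `min_transcript_len`. The first matching rule (in that order) is recorded
#' as the exclusion reason.
#'
#' @param genes feature table of the genes to filter.
#' @param all_features feature table of all annotations (must contain the
#'   genes themselves; IR rows are ignored for the overlap test).
#' @param min_transcript_len minimum gene length in bp (default 1 kb).
#' @param organellar_chroms chromosome names considered organellar.
#' @return list with elements `kept` (feature table) and `excluded`
#'   (`data.table` of `id`, `reason` in {organellar, overlap, short}).
#' @export
filter_genes_for_profiles <- function(genes, all_features,
                                      min_transcript_len = 1000,
                                      organellar_chroms = c("ChrM", "ChrC",
                                                            "mitochondria",
                                                            "chloroplast")) {
  genes <- as.data.table(genes)
  others <- as.data.table(all_features)[category != "IR"]
  if (nrow(genes) == 0L)
    return(list(kept = genes[], excluded = data.table(id = character(),
                                                      reason = character())))

  organellar <- genes$chrom %in% organellar_chroms

  # >= 1 bp intersection with any other (non-self) non-IR feature
  ov <- rep(FALSE, nrow(genes))
  if (nrow(others) > 0L) {
    qry <- IRanges::IRanges(start = genes$start + 1, end = genes$end)
    sbj <- IRanges::IRanges(start = others$start + 1, end = others$end)
    hits <- IRanges::findOverlaps(qry, sbj)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    same_chrom <- genes$chrom[qh] == others$chrom[sh]
    not_self <- genes$id[qh] != others$id[sh]
    ov[unique(qh[same_chrom & not_self])] <- TRUE
  }

  short <- (genes$end - genes$start) < min_transcript_len

  reason <- rep(NA_character_, nrow(genes))
  reason[short] <- "short"
  reason[ov] <- "overlap"
  reason[organellar] <- "organellar"

  keep_idx <- is.na(reason)
  list(kept = genes[keep_idx],
       excluded = data.table(id = genes$id[!keep_idx],
                             reason = reason[!keep_idx]))
}

#' Write features as BED6
#'
#' @param features feature table.
#' @param path output path.
#' @param name `"id"` or `"category"`: which column fills the BED name field
#'   (merged chromatin-state / IR emitters put the class in the name column).
#' @return invisibly, the path.
#' @export
write_bed6 <- function(features, path, name = c("id", "category")) {
  name <- match.arg(name)
  dt <- as.data.table(features)
  nm <- if (name == "id") dt$id else dt$category
  out <- data.table(dt$chrom, format(dt$start, scientific = FALSE, trim = TRUE),
                    format(dt$end, scientific = FALSE, trim = TRUE),
                    nm, 0L, dt$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write chromatin-state segments as BED-like TSV (state in name column)
#' @param segments state segment table (`chrom`, `start`, `end`, `state`).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_states_bed <- function(segments, path) {
  dt <- as.data.table(segments)
  out <- data.table(dt$chrom, format(dt$start, scientific = FALSE, trim = TRUE),
                    format(dt$end, scientific = FALSE, trim = TRUE),
                    dt$state, 0L, ".")
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load chromatin-state segments from a BED-like file
#' @param path BED file whose name column holds the state (CS1..CS4).
#' @return `data.table` with columns chrom, start, end, state.
#' @export
load_chromatin_states <- function(path) {
  .prescan_lines(path, "bed")
  gr <- rtracklayer::import(path, format = "bed")
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             state = as.character(gr$name))
}
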