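# Genome coordinate frame: chromosome sizes plus centromere and
# heterochromatin intervals. All coordinates in the package are 0-based
# half-open [start, end); readers of 1-based formats convert on input.

#' Construct a genome model
#'
#' The genome model is the coordinate frame for every other object in the
#' package: an ordered set of chromosomes with lengths, one centromere
#' interval per (nuclear) chromosome, and an optional set of heterochromatin
#' blocks (e.g. pericentromeric regions and knobs).
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp > 0);
#'   names must be unique and order is preserved.
#' @param centromeres optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open), at most one row per chromosome.
#' @param heterochromatin optional data.frame with columns `chrom`, `start`,
#'   `end`; may be empty or `NULL`.
#' @return an object of class `GenomeModel`.
#' @examples
#' gm <- genome_model(data.frame(name = "chr1", length = 1e5),
#'                    centromeres = data.frame(chrom = "chr1",
#'                                             start = 4e4, end = 6e4))
#' chrom_lengths(gm)
#' @export
genome_model <- function(chromosomes, centromeres = NULL,
                         heterochromatin = NULL) {
  chromosomes <- as.data.table(chromosomes)
  if (!all(c("name", "length") %in% names(chromosomes)))
    stopf("`chromosomes` needs columns 'name' and 'length'")
  chromosomes <- chromosomes[, .(name = as.character(name),
                                 length = as.numeric(length))]
  if (anyDuplicated(chromosomes$name))
    stopf("chromosome names must be unique")
  if (any(!is.finite(chromosomes$length)) || any(chromosomes$length <= 0))
    stopf("all chromosome lengths must be positive")
  lens <- setNames(chromosomes$length, chromosomes$name)

  centromeres <- .as_interval_dt(centromeres, lens, "centromeres")
  if (anyDuplicated(centromeres$chrom))
    stopf("at most one centromere per chromosome")
  heterochromatin <- .as_interval_dt(heterochromatin, lens, "heterochromatin")

  structure(list(chromosomes = chromosomes,
                 centromeres = centromeres,
                 heterochromatin = heterochromatin),
            class = "GenomeModel")
}

.as_interval_dt <- function(x, lens, what) {
  if (is.null(x) || NROW(x) == 0L)
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric()))
  x <- as.data.table(x)
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stopf("`%s` needs columns chrom, start, end", what)
  x <- x[, .(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end))]
  bad <- setdiff(x$chrom, names(lens))
  if (length(bad))
    stopf("%s reference unknown chromosomes: %s", what,
          paste(bad, collapse = ", "))
  if (any(x$start < 0 | x$end > lens[x$chrom] | x$start >= x$end))
    stopf("%s intervals must satisfy 0 <= start < end <= chromosome length",
          what)
  x[]
}

#' Chromosome lengths of a genome model
#' @param genome a `GenomeModel`.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "GenomeModel"))
  setNames(genome$chromosomes$length, genome$chromosomes$name)
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosome(s), %.3g Mb total\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6))
  cat(sprintf("  centromeres: %d; heterochromatin blocks: %d\n",
              nrow(x$centromeres), nrow(x$heterochromatin)))
  invisible(x)
}

# validate a feature-like table against the genome; returns invisibly
.check_features_in_genome <- function(features, genome) {
  lens <- chrom_lengths(genome)
  bad <- setdiff(unique(features$chrom), names(lens))
  if (length(bad))
    stopf("features reference unknown chromosomes: %s",
          paste(bad, collapse = ", "))
  if (any(features$start < 0 | features$end > lens[features$chrom] |
          features$start >= features$end))
    stopf("feature intervals must satisfy 0 <= start < end <= chromosome length")
  invisible(features)
}
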