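# FPKM table management: replicate-consistency filtering, per-tissue means,
# expression / length binning, differential gene-set selection, and group
# expression summaries.

TISSUES <- c("dividing", "nondividing")

#' Construct an expression table
#'
#' Long-format FPKM records, one row per (gene, tissue, replicate). A gene
#' is "expressed" iff its FPKM is > 0 in at least one library.
#'
#' @param data data.frame with columns `gene_id`, `tissue` (`"dividing"` or
#'   `"nondividing"`), `replicate` (integer), `fpkm` (>= 0).
#' @return a `data.table` of class `ExpressionTable`.
#' @export
expression_table <- function(data) {
  dt <- as.data.table(data)
  need <- c("gene_id", "tissue", "replicate", "fpkm")
  if (!all(need %in% names(dt)))
    stopf("expression data needs columns %s", paste(need, collapse = ", "))
  dt <- dt[, .(gene_id = as.character(gene_id), tissue = as.character(tissue),
               replicate = as.integer(replicate), fpkm = as.numeric(fpkm))]
  if (any(!dt$tissue %in% TISSUES))
    stopf("tissue must be one of: %s", paste(TISSUES, collapse = ", "))
  if (any(is.na(dt$fpkm) | dt$fpkm < 0))
    stopf("FPKM values must be >= 0")
  if (anyDuplicated(dt[, .(gene_id, tissue, replicate)]))
    stopf("duplicate (gene, tissue, replicate) records")
  setattr(dt, "class", c("ExpressionTable", class(dt)))
  dt[]
}

#' Read an expression table from TSV
#' @param path TSV with columns gene_id, tissue, replicate, fpkm.
#' @return an `ExpressionTable`.
#' @export
read_expression_tsv <- function(path) {
  expression_table(fread(path, sep = "\t"))
}

#' Per-tissue mean FPKM and expressed status
#'
#' @param expr an `ExpressionTable`.
#' @return `data.table` with columns `gene_id`, `dividing`, `nondividing`
#'   (arithmetic means over that tissue's replicates) and `expressed`
#'   (FPKM > 0 in at least one library).
#' @export
expression_means <- function(expr) {
  dt <- as.data.table(expr)
  m <- dcast(dt, gene_id ~ tissue, value.var = "fpkm", fun.aggregate = mean)
  for (tt in TISSUES) if (!tt %in% names(m)) m[, (tt) := NA_real_]
  ex <- dt[, .(expressed = any(fpkm > 0)), by = gene_id]
  out <- merge(m, ex, by = "gene_id", sort = TRUE)
  out[, .(gene_id, dividing, nondividing, expressed)]
}

#' Replicate-consistency verdict for one tissue's FPKM pair
#'
#' A gene's tissue measurement is discarded when the two replicates show
#' unexpected variation, under three rules combined with OR (first match
#' reported): (i) absolute FPKM difference > 1.0; (ii) the absolute
#' difference exceeds a third of the smaller replicate (evaluated only when
#' both are > 0); (iii) FPKM is zero in exactly one replicate.
#'
#' @param fpkm_rep1,fpkm_rep2 non-negative FPKM values (vectorized).
#' @return character vector: `"keep"`, `"discard_i"`, `"discard_ii"` or
#'   `"discard_iii"`.
#' @export
replicate_consistency_filter <- function(fpkm_rep1, fpkm_rep2) {
  r1 <- as.numeric(fpkm_rep1); r2 <- as.numeric(fpkm_rep2)
  if (length(r1) != length(r2)) stopf("replicate vectors differ in length")
  if (any(is.na(r1) | is.na(r2) | r1 < 0 | r2 < 0))
    stopf("validation error: FPKM values must be >= 0")
  d <- abs(r1 - r2)
  mn <- pmin(r1, r2)
  out <- rep("keep", length(r1))
  rule_iii <- xor(r1 == 0, r2 == 0)
  rule_ii <- mn > 0 & d / mn > 1 / 3
  rule_i <- d > 1.0
  out[rule_iii] <- "discard_iii"
  out[rule_ii] <- "discard_ii"
  out[rule_i] <- "discard_i"      # precedence i > ii > iii for reporting
  out
}

#' Apply the replicate-consistency filter to a whole table
#'
#' A gene is discarded overall if it is discarded in either tissue.
#'
#' @param expr an `ExpressionTable` with two replicates per tissue.
#' @return `data.table` with columns `gene_id`, per-tissue verdicts
#'   (`verdict_dividing`, `verdict_nondividing`) and logical `keep`.
#' @export
filter_expression <- function(expr) {
  dt <- as.data.table(expr)
  wide <- dcast(dt, gene_id ~ tissue + replicate, value.var = "fpkm")
  need <- c("dividing_1", "dividing_2", "nondividing_1", "nondividing_2")
  miss <- setdiff(need, names(wide))
  if (length(miss))
    stopf("filter needs two replicates per tissue; missing: %s",
          paste(miss, collapse = ", "))
  out <- data.table(
    gene_id = wide$gene_id,
    verdict_dividing = replicate_consistency_filter(wide$dividing_1,
                                                    wide$dividing_2),
    verdict_nondividing = replicate_consistency_filter(wide$nondividing_1,
                                                       wide$nondividing_2))
  out[, keep := verdict_dividing == "keep" & verdict_nondividing == "keep"]
  out[]
}

#' Expression bin of a mean FPKM value
#'
#' Bins are half-open `(lo, hi]`: (30, Inf), (20, 30], (10, 20], (5, 10],
#' (1, 5], (0, 1]. A mean of 0 (unexpressed) maps to `NA` — such genes are
#' excluded upstream.
#'
#' @param mean_fpkm non-negative mean FPKM (vectorized).
#' @return factor with levels `"0-1"`, `"1-5"`, `"5-10"`, `"10-20"`,
#'   `"20-30"`, `">30"`.
#' @export
assign_expression_bin <- function(mean_fpkm) {
  if (any(mean_fpkm < 0, na.rm = TRUE)) stopf("mean FPKM must be >= 0")
  cut(as.numeric(mean_fpkm), breaks = c(0, 1, 5, 10, 20, 30, Inf),
      right = TRUE,
      labels = c("0-1", "1-5", "5-10", "10-20", "20-30", ">30"))
}

#' Length bin of a gene
#'
#' Bins are `[lo, hi)` at 1/2/3/4 kb boundaries, so 1000 bp falls in
#' `"1-2kb"` and 4000 bp in `">4kb"`.
#'
#' @param gene_length positive length in bp (vectorized).
#' @return factor with levels `"<1kb"`, `"1-2kb"`, `"2-3kb"`, `"3-4kb"`,
#'   `">4kb"`.
#' @export
assign_length_bin <- function(gene_length) {
  if (any(gene_length <= 0, na.rm = TRUE)) stopf("gene length must be > 0")
  cut(as.numeric(gene_length), breaks = c(0, 1000, 2000, 3000, 4000, Inf),
      right = FALSE,
      labels = c("<1kb", "1-2kb", "2-3kb", "3-4kb", ">4kb"))
}

#' Select fold-change gene sets between tissues
#'
#' A gene is up in dividing tissue iff its dividing mean is at least `fold`
#' times its non-dividing mean and is positive; a zero denominator counts as
#' exceeding any fold (ON/OFF genes are the strongest members). Symmetric
#' for the other set. Genes with both means 0 belong to neither.
#'
#' @param means per-gene means from [expression_means()] (or an
#'   `ExpressionTable`, which is reduced first).
#' @param fold fold-change threshold (default 5).
#' @return list of character vectors `up_in_dividing`, `up_in_nondividing`.
#' @export
select_fold_change_sets <- function(means, fold = 5) {
  m <- if (inherits(means, "ExpressionTable")) expression_means(means)
       else as.data.table(means)
  up_div <- m$dividing > 0 & m$dividing >= fold * m$nondividing
  up_non <- m$nondividing > 0 & m$nondividing >= fold * m$dividing
  list(up_in_dividing = m$gene_id[up_div],
       up_in_nondividing = m$gene_id[up_non])
}

#' Select ON/OFF gene sets between tissues
#'
#' ON means mean FPKM strictly above `on_thresh`; OFF strictly below
#' `off_thresh` (strict inequalities).
#'
#' @inheritParams select_fold_change_sets
#' @param on_thresh,off_thresh FPKM thresholds (defaults 3 and 1).
#' @return list of character vectors `on_div_off_nondiv`,
#'   `on_nondiv_off_div`.
#' @export
select_on_off_sets <- function(means, on_thresh = 3, off_thresh = 1) {
  m <- if (inherits(means, "ExpressionTable")) expression_means(means)
       else as.data.table(means)
  list(on_div_off_nondiv =
         m$gene_id[m$dividing > on_thresh & m$nondividing < off_thresh],
       on_nondiv_off_div =
         m$gene_id[m$nondividing > on_thresh & m$dividing < off_thresh])
}

#' Summarize gene groups by per-tissue total expression
#'
#' Per group, totals are the sums of member per-tissue mean FPKM; the
#' dividing / non-dividing ratio is computed from the unrounded totals and
#' is `NA` when the non-dividing total is 0. [render_group_summary()]
#' applies the conventional rounding (totals to 1 decimal, ratios to 2).
#'
#' @param expr an `ExpressionTable` (or a means table).
#' @param groups named list: group label -> character vector of gene ids.
#' @return `data.table` with columns `group`, `dividing_total`,
#'   `nondividing_total`, `ratio`.
#' @export
summarize_gene_groups <- function(expr, groups) {
  m <- if (inherits(expr, "ExpressionTable")) expression_means(expr)
       else as.data.table(expr)
  all_ids <- unlist(groups, use.names = FALSE)
  missing <- setdiff(all_ids, m$gene_id)
  if (length(missing))
    stopf("genes missing from the expression table: %s",
          paste(missing, collapse = ", "))
  rows <- lapply(names(groups), function(lab) {
    sub <- m[m$gene_id %in% groups[[lab]]]
    dv <- sum(sub$dividing); nd <- sum(sub$nondividing)
    data.table(group = lab, dividing_total = dv, nondividing_total = nd,
               ratio = if (nd > 0) dv / nd else NA_real_)
  })
  rbindlist(rows)
}

#' Round a group summary for display
#' @param summary output of [summarize_gene_groups()].
#' @return `data.table` with totals at 1 decimal and ratios at 2.
#' @export
render_group_summary <- function(summary) {
  s <- copy(as.data.table(summary))
  s[, `:=`(dividing_total = round(dividing_total, 1),
           nondividing_total = round(nondividing_total, 1),
           ratio = round(ratio, 2))]
  s[]
}

#' Worked-example expression data: histone H3 variants and chaperones
#'
#' Published per-tissue mean FPKM values for the Arabidopsis histone H3
#' variant genes (H3.3: HTR4/HTR5/HTR8; H3.1: HTR2/HTR3/HTR13/HTR9/HTR1),
#' the centromeric cenH3 (HTR12) and candidate H3 chaperone genes, in
#' dividing (meristem + primordia) versus non-dividing (mature leaf)
#' tissue. Used as a worked example for [summarize_gene_groups()].
#'
#' @return list with `expr` (an `ExpressionTable` where both replicates
#'   equal the reported tissue mean) and `groups` (named list of gene ids).
#' @export
example_h3_expression <- function() {
  path <- system.file("extdata", "h3_gene_fpkm.tsv", package = "h3profiler")
  dt <- fread(path, sep = "\t")
  long <- rbindlist(lapply(1:2, function(r)
    rbindlist(list(
      dt[, .(gene_id, tissue = "dividing", replicate = r, fpkm = dividing)],
      dt[, .(gene_id, tissue = "nondividing", replicate = r,
             fpkm = nondividing)]))))
  groups <- split(dt$gene_id, dt$group)
  list(expr = expression_table(long), groups = groups)
}
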