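# fixtures built in code

toy_genome <- function(lens = c(Chr1 = 10000, Chr2 = 8000)) {
  genome_model(data.frame(name = names(lens), length = unname(lens)))
}

uniform_track <- function(genome, value = 1, step = 10, normalized = TRUE) {
  lens <- chrom_lengths(genome)
  vals <- lapply(lens, function(l) rep(value, ceiling(l / step)))
  signal_track(vals, step = step, chrom_lengths = lens,
               library_size = 1e6, normalized = normalized)
}

random_track <- function(genome, seed, step = 10, normalized = TRUE) {
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    vals <- lapply(lens, function(l) runif(ceiling(l / step), 0, 10))
    signal_track(vals, step = step, chrom_lengths = lens,
                 library_size = 1e6, normalized = normalized)
  })
}

# small long-format expression table
toy_expression <- function(df) {
  # df: gene_id, d1, d2, n1, n2
  expression_table(rbind(
    data.frame(gene_id = df$gene_id, tissue = "dividing", replicate = 1,
               fpkm = df$d1),
    data.frame(gene_id = df$gene_id, tissue = "dividing", replicate = 2,
               fpkm = df$d2),
    data.frame(gene_id = df$gene_id, tissue = "nondividing", replicate = 1,
               fpkm = df$n1),
    data.frame(gene_id = df$gene_id, tissue = "nondividing", replicate = 2,
               fpkm = df$n2)))
}

# small synthetic config for fast tests
small_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 2L, chrom_length = 1e5,
         centromere_fraction = 0.12, knob_length = 5e3,
         n_genes = 50L, n_tes = 16L, n_sites = 150L,
         gene_meanlog = log(1200), te_meanlog = log(800), gap_mean = 300),
    list(...))
  do.call(synthetic_config, args)
}
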