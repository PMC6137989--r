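# Shared in-code fixtures.

# a config small enough for unit tests (capacity: 25 genes/chromosome)
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length = 3e5, n_genes = 50),
    list(...))
  do.call(sim_config, args)
}

# single-chromosome track from a plain count vector
make_track <- function(counts, W = 200, id = "t", chrom = "chr1") {
  coverage_track(setNames(list(counts), chrom), W, sample_id = id)
}

# hand-built annotation with the chrom_lengths attribute attached
make_genes <- function(gene_id, chrom, start, end, strand,
                       biotype = "PCG", chrom_lengths = NULL) {
  g <- gene_model(gene_id, chrom, start, end, strand, biotype)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(g$end + 2000, g$chrom, max)
  }
  attr(g, "chrom_lengths") <- chrom_lengths
  g
}

make_truth <- function(genes, class = "k2_tss", de = "null",
                       change = "none", zero = FALSE) {
  data.frame(gene_id = genes$gene_id,
             planted_class = rep_len(class, nrow(genes)),
             planted_biotype = genes$biotype,
             planted_zero = rep_len(zero, nrow(genes)),
             planted_de = rep_len(de, nrow(genes)),
             planted_h2az_change = rep_len(change, nrow(genes)),
             stringsAsFactors = FALSE)
}
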