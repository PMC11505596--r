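# Shared fixtures: all built in code at test time.

# a small, fast simulation world used across tests
small_sim <- function(seed = 1, ...) {
  args <- list(Ne_L = 6000, Ne_S = 1000, mu = 2.5e-6, s = 10 / (4 * 6000),
               n_chrom = 4, chrom_length = 2e6, n_genes = 40,
               intergenic_len = 20000, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# write a toy VCF from explicit record lines
write_toy_vcf <- function(lines, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Coding effect tag">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines), path)
  path
}

# brute-force mean pairwise Hamming distance over all chromosome pairs of a
# 0/1 haplotype matrix (rows = chromosomes); the independent oracle for pi
brute_force_pairwise <- function(hap) {
  n <- nrow(hap)
  tot <- 0L
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n))
    tot <- tot + sum(hap[a, ] != hap[b, ])
  list(total_diffs = tot, mean_pairwise = tot / choose(n, 2))
}

# variant table straight from a haplotype matrix (single population "pop")
variants_from_haplotypes <- function(hap, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq_len(ncol(hap)),
             ref = "A", alt = "G", class = "intron", gene_id = NA,
             j_pop = colSums(hap), n_pop = nrow(hap))
}
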