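test_that("read_vcf counts alleles, filters to biallelic autosomal SNVs, sorts", {
  samples <- c("s1", "s2", "s3")
  p <- write_toy_vcf(c(
    "chr2\t50\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",   # j=3 over s2,s3? see pops below
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",  # j (s1,s2) = 3, n = 4
    "chr1\t200\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0", # triallelic: dropped
    "chr1\t300\t.\tGA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",  # indel: dropped
    "chrX\t400\t.\tA\tC\t.\tPASS\t.\tGT\t0/1\t0/1\t0/1",   # non-autosomal
    "chr1\t500\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t0/1\t1/1"    # missing reduces n
  ), samples)
  v <- read_vcf(p, populations = list(A = c("s1", "s2"), B = "s3"))
  expect_equal(nrow(v), 3L)
  expect_equal(v$chrom, c("chr1", "chr1", "chr2"))  # sorted by (chrom, pos)
  expect_equal(v$pos, c(100L, 500L, 50L))
  r100 <- v[v$pos == 100, ]
  expect_equal(r100$j_A, 3L); expect_equal(r100$n_A, 4L)
  expect_equal(r100$j_B, 0L); expect_equal(r100$n_B, 2L)
  r500 <- v[v$pos == 500, ]
  expect_equal(r500$j_A, 1L); expect_equal(r500$n_A, 2L)  # ./. dropped from n
  expect_equal(r500$j_B, 2L)
  expect_error(read_vcf(p, populations = list(A = c("s1", "nope"))),
               "nope")
})

test_that("read_vcf returns an empty table for an empty VCF body", {
  p <- write_toy_vcf(character(0), c("s1"))
  v <- read_vcf(p, populations = list(A = "s1"))
  expect_equal(nrow(v), 0L)
})

test_that("VCF round trip preserves counts, alleles and effect tags", {
  cfg <- small_sim(seed = 11, n_genes = 10, chrom_length = 1.5e6, n_chrom = 2,
                   mu = 5e-7)
  ds <- generate_dataset(cfg, scores = FALSE)
  p <- tempfile(fileext = ".vcf")
  write_vcf(ds$variants, p, n_diploids = c(large = 10, small = 10))
  v2 <- read_vcf(p, populations = list(large = paste0("large_", 1:10),
                                       small = paste0("small_", 1:10)))
  expect_equal(nrow(v2), nrow(ds$variants))
  for (col in c("chrom", "ref", "alt", "effect"))
    expect_equal(v2[[col]], ds$variants[[col]])
  expect_equal(v2$pos, as.integer(ds$variants$pos))
  for (col in c("j_large", "n_large", "j_small", "n_small"))
    expect_equal(v2[[col]], as.integer(ds$variants[[col]]))
})

test_that("site class map merges overlapping intervals and honours L overrides", {
  m <- site_class_map(list(
    intron = data.frame(chrom = "chr1", start0 = c(0, 50), end0 = c(100, 150))))
  expect_equal(length(m$intervals$intron), 1L)
  expect_equal(class_L(m, "intron"), 150)
  m2 <- site_class_map(
    list(exome = data.frame(chrom = "chr1", start0 = 0, end0 = 300)),
    L = c(nonsynonymous = 1000.5, synonymous = 200))
  expect_equal(class_L(m2, "nonsynonymous"), 1000.5)  # fractional pass-through
  expect_equal(class_L(m2, "exome"), 300)             # own intervals win
  expect_error(class_L(m, "intergenic"), "absent")
  expect_error(site_class_map(list(bogus = data.frame(
    chrom = "chr1", start0 = 0, end0 = 10))), "unknown site class")
  bad <- data.frame(chrom = "chr1", start0 = 10, end0 = 10)
  expect_error(site_class_map(list(intron = bad)), "end <= start")
})

test_that("read_site_classes reads BED and sums disjoint intervals", {
  p1 <- tempfile(); p2 <- tempfile()
  writeLines(c("chr1\t0\t100", "chr1\t50\t150"), p1)   # overlapping: merge
  writeLines(c("chr1\t200\t300", "chr2\t0\t50"), p2)   # disjoint: sum
  m <- read_site_classes(list(intron = p1, intergenic = p2))
  expect_equal(class_L(m, "intron"), 150)
  expect_equal(class_L(m, "intergenic"), 150)
})

test_that("assign_site_class follows half-open BED semantics and effect tags", {
  m <- site_class_map(list(
    intron = data.frame(chrom = "chr1", start0 = 100, end0 = 200),
    exome = data.frame(chrom = "chr1", start0 = 300, end0 = 400)))
  v <- data.frame(chrom = "chr1", pos = c(150, 200, 201, 350, 360, 10),
                  ref = "A", alt = "G",
                  effect = c(NA, NA, NA, "missense_variant",
                             "synonymous_variant", NA),
                  j_p = 1, n_p = 4)
  out <- assign_site_class(v, m)
  # 1-based 150 = 0-based 149, inside [100,200); 200 -> 199 inside; 201 -> 200 out
  expect_equal(out$class,
               c("intron", "intron", "unassigned", "nonsynonymous",
                 "synonymous", "unassigned"))
  # order independence
  perm <- sample(nrow(v))
  out2 <- assign_site_class(v[perm, ], m)
  expect_equal(out2$class, out$class[perm])
  # intron/intergenic overlap is a map inconsistency
  m_bad <- site_class_map(list(
    intron = data.frame(chrom = "chr1", start0 = 100, end0 = 200),
    intergenic = data.frame(chrom = "chr1", start0 = 150, end0 = 250)))
  expect_error(assign_site_class(v, m_bad), "inconsistency")
})

test_that("distal intergenic filter keeps only windows far from genes", {
  m <- site_class_map(list(
    intergenic = data.frame(chrom = "chr1", start0 = c(0, 3e6), end0 = c(1e6, 4e6))))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start0 = 1.2e6,
                      end0 = 1.3e6, feature = "cds")
  m2 <- distal_intergenic(m, genes, distance = 1e6)
  # of [0, 1e6): only positions < 0.2e6 are >= 1 Mb from the gene at 1.2e6;
  # [3e6, 4e6) is entirely >= 1 Mb beyond the gene end at 1.3e6
  expect_equal(class_L(m2, "intergenic_distal"), 0.2e6 + 1e6)
  # variants in the distal windows get the subclass, which still counts as
  # intergenic for pooled estimates
  v <- data.frame(chrom = "chr1", pos = c(100, 0.5e6, 3.5e6), ref = "A",
                  alt = "G", j_p = 1, n_p = 4)
  out <- assign_site_class(v, m2)
  expect_equal(out$class, c("intergenic_distal", "intergenic",
                            "intergenic_distal"))
  expect_equal(class_pi(out, "intergenic", 1e6, "p")$n_snvs, 3L)
  expect_equal(class_pi(out, "intergenic_distal", 1e6, "p")$n_snvs, 2L)
})

test_that("score tracks expand per position and expression reads with last-wins", {
  p <- tempfile()
  writeLines("chr1\t10\t13\t2.5", p)
  sc <- read_scores(p)
  ex <- expand_scores(sc)
  expect_equal(ex$pos0, c(10L, 11L, 12L))
  expect_equal(ex$score, rep(2.5, 3))
  p0 <- tempfile(); writeLines(character(0), p0)
  expect_equal(nrow(read_scores(p0)), 0L)
  pe <- tempfile()
  writeLines(c("gene_id\texpression", "g1\t5.0", "g2\t6.5", "g1\t4.0", "g3\t7"), pe)
  expect_warning(e <- read_expression(pe), "duplicate")
  expect_equal(length(e), 3L)
  expect_equal(unname(e["g1"]), 4.0)
})
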