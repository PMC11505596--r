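test_that("site_pi equals the fraction of differing chromosome pairs", {
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(1, 4), 0.5)      # 3 of 6 pairs differ
  expect_equal(site_pi(2, 4), 2 / 3)    # 4 of 6 pairs differ
  expect_equal(site_pi(4, 4), 0)        # fixed in sample
  expect_error(site_pi(0, 1), "n >= 2")
  expect_error(site_pi(5, 4), "j <= n")
})

test_that("class_pi is the site_pi sum over the class divided by L", {
  v <- data.frame(chrom = "chr1", pos = c(10, 20, 30), ref = "A", alt = "G",
                  class = c("intron", "intron", "intergenic"),
                  j_p = c(1, 2, 1), n_p = c(4, 4, 4))
  est <- class_pi(v, "intron", 100, "p")
  expect_equal(est$pi, (0.5 + 2 / 3) / 100)
  expect_equal(est$n_snvs, 2L)
  # no SNVs in class -> pi = 0
  expect_equal(class_pi(v, "exome", 1000, "p")$pi, 0)
  # doubling L halves pi
  expect_equal(class_pi(v, "intron", 200, "p")$pi, est$pi / 2)
  expect_error(class_pi(v, "intron", 0, "p"), "positive")
  expect_error(class_pi(v, "intron", 100, "q"), "not present")
})

test_that("streaming pi numerator equals brute-force pairwise differences", {
  # oracle equivalence on random genotype matrices
  set.seed(7)
  for (rep in 1:30) {
    n_chr <- 2 * sample(2:5, 1)              # up to 10 chromosomes
    n_sites <- sample(1:50, 1)
    hap <- matrix(rbinom(n_chr * n_sites, 1, runif(1, 0.1, 0.9)),
                  nrow = n_chr)
    v <- variants_from_haplotypes(hap)
    bf <- brute_force_pairwise(hap)
    # integer identity: sum_site j(n-j) = total differing pairs
    expect_identical(as.integer(sum(v$j_pop * (n_chr - v$j_pop))), bf$total_diffs)
    est <- class_pi(v, "intron", n_sites, "pop")
    expect_equal(est$pi * n_sites, bf$mean_pairwise, tolerance = 1e-12)
  }
})

test_that("site_pi is an unbiased estimator of 2q(1-q)", {
  set.seed(99)
  for (q in c(0.05, 0.3)) {
    n <- 10
    j <- rbinom(1e5, n, q)
    x <- site_pi(j, n)
    mc_se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 2 * q * (1 - q)), 3 * mc_se)
  }
})

test_that("partition_blocks places variants and apportions interval lengths", {
  m <- site_class_map(list(
    intron = data.frame(chrom = "chr1", start0 = 999990, end0 = 1000010)))
  v <- data.frame(chrom = "chr1", pos = c(1000000, 1000001), ref = "A",
                  alt = "G", class = "intron", j_p = c(1, 1), n_p = c(4, 4))
  bi <- partition_blocks(v, m)
  expect_equal(nrow(bi$blocks), 2L)
  expect_equal(bi$blocks$ordinal, c(0, 1))      # pos 1e6 -> block 0, 1e6+1 -> block 1
  expect_equal(bi$block_of, c(1L, 2L))
  expect_equal(unname(bi$lengths[, "intron"]), c(10, 10))  # split 10/10
  # empty variant list still yields blocks with correct lengths
  bi0 <- partition_blocks(v[0, ], m)
  expect_equal(sum(bi0$lengths[, "intron"]), 20)
})

test_that("block lengths sum to L and every variant gets exactly one block", {
  cfg <- small_sim(seed = 5, n_genes = 20, mu = 5e-7)
  ds <- generate_dataset(cfg, scores = FALSE)
  bi <- partition_blocks(ds$variants, ds$map)
  for (cl in c("intron", "intergenic", "exome"))
    expect_equal(sum(bi$lengths[, cl]), class_L(ds$map, cl))
  expect_equal(length(bi$block_of), nrow(ds$variants))
  expect_true(all(bi$block_of >= 1 & bi$block_of <= nrow(bi$blocks)))
})

test_that("block bootstrap is deterministic and zero-variance on identical blocks", {
  stat_const <- function(idx) length(idx)          # block count: constant
  b1 <- block_bootstrap(10, stat_const, B = 50, seed = 3)
  expect_equal(b1$se, 0)
  # identical blocks: any pooled ratio statistic is constant
  num <- rep(2.5, 8); den <- rep(100, 8)
  stat_ratio <- function(idx) sum(num[idx]) / sum(den[idx])
  expect_equal(block_bootstrap(8, stat_ratio, B = 100, seed = 1)$se, 0)
  # same seed -> identical replicates
  stat_rand <- function(idx) mean(idx)
  r1 <- block_bootstrap(20, stat_rand, B = 100, seed = 9)
  r2 <- block_bootstrap(20, stat_rand, B = 100, seed = 9)
  expect_identical(r1$replicates, r2$replicates)
  expect_error(block_bootstrap(1, stat_const, B = 10), "at least 2")
})

test_that("undefined replicates are dropped up to 10%, then error", {
  # statistic undefined whenever block 1 is missed: frequent -> error
  stat <- function(idx) if (1 %in% idx) 1 else NA_real_
  set.seed(1)
  expect_error(block_bootstrap(50, stat, B = 100, seed = 2), "undefined")
  # rare undefined: message + exclusion
  stat2 <- function(idx) if (all(idx == 3)) NA_real_ else mean(idx)
  expect_message(b <- block_bootstrap(3, stat2, B = 200, seed = 4),
                 "excluded")
  expect_true(is.finite(b$se))
})

test_that("bootstrap SE is calibrated against across-dataset variation", {
  # ~100 blocks; compare bootstrap SE of neutral pi on one dataset with the
  # empirical SD of pi across independently regenerated datasets
  mk <- function(seed) {
    cfg <- sim_config(Ne_L = 2000, Ne_S = 1000, mu = 5e-7, s = 0,
                      n_chrom = 25, chrom_length = 4e6, n_genes = 100,
                      cds_len = 300, intron_len = 2000, intergenic_len = 0,
                      seed = seed)
    generate_dataset(cfg, scores = FALSE)
  }
  ds <- mk(1)
  bi <- partition_blocks(ds$variants, ds$map)
  expect_gte(nrow(bi$blocks), 100)
  div <- diversity_with_bootstrap(bi, ds$map, classes = "intron",
                                  B = 200, seed = 1)
  se_boot <- div$se[div$population == "large"]
  pis <- vapply(1:100, function(s) {
    d <- mk(s + 100)
    class_pi(d$variants, "intron", class_L(d$map, "intron"), "large")$pi
  }, numeric(1))
  expect_lt(se_boot / sd(pis), 1.5)
  expect_gt(se_boot / sd(pis), 1 / 1.5)
})
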