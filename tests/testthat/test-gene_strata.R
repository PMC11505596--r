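test_that("constraint proportion counts strictly above-threshold positions", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start0 = 0, end0 = 10,
                      feature = "cds")
  mk_scores <- function(vals) {
    s <- data.table::data.table(chrom = "chr1", start0 = 0:(length(vals) - 1),
                                end0 = 1:length(vals), score = vals)
    class(s) <- c("score_track", class(s))
    s
  }
  # 3 of 10 positions above 2.0
  cp <- suppressMessages(gene_constraint_proportion(
    genes, mk_scores(c(2.5, 2.5, 2.5, rep(1, 7)))))
  expect_equal(cp$constraint_prop, 0.3)
  # exactly 2.0 is NOT constrained (strict inequality)
  cp2 <- suppressMessages(gene_constraint_proportion(
    genes, mk_scores(rep(2.0, 10))))
  expect_equal(cp2$constraint_prop, 0)
  # all below threshold -> 0; positions without scores count as unconstrained
  cp3 <- suppressMessages(gene_constraint_proportion(
    genes, mk_scores(c(3, 3))[1:2]))
  expect_equal(cp3$constraint_prop, 0.2)
  expect_error(suppressMessages(gene_constraint_proportion(
    data.frame(gene_id = "g", chrom = "c", start0 = 0, end0 = 5,
               feature = "intron"), mk_scores(1))), "no 'cds'")
})

test_that("equal-count binning reproduces the published stratum counts", {
  # 14,870 genes at 1000/bin -> 15 strata (remainder 870 stands alone)
  st <- equal_count_bins(runif(14870), bin_size = 1000)
  expect_equal(length(unique(st)), 15L)
  expect_equal(max(table(st)), 1000)
  # 9,089 genes -> 9 strata (remainder 89 merges into the last)
  st2 <- equal_count_bins(runif(9089), bin_size = 1000)
  expect_equal(length(unique(st2)), 9L)
  expect_equal(as.integer(table(st2))[9], 1089L)
  # 10 genes at bin 5 -> 5/5
  st3 <- equal_count_bins(1:10, bin_size = 5)
  expect_equal(as.integer(table(st3)), c(5L, 5L))
  expect_warning(equal_count_bins(1:3, bin_size = 5), "single stratum")
  # strata follow the sort order of the stratifier
  v <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6)
  st4 <- equal_count_bins(v, bin_size = 5)
  expect_true(all(v[st4 == 1] < min(v[st4 == 2])))
  # partition: every gene in exactly one stratum
  expect_equal(sum(table(st4)), 10)
})

test_that("spearman_test matches exact ranks and cor.test", {
  sp <- spearman_test(1:4, c(2, 1, 4, 3), n_perm = 999, seed = 1)
  expect_equal(sp$rho, 0.6)
  expect_equal(sp$p_value, cor.test(1:4, c(2, 1, 4, 3),
                                    method = "spearman")$p.value,
               tolerance = 0.2)  # permutation vs exact, small n
  set.seed(5)
  x <- rnorm(20); y <- x + rnorm(20)
  sp2 <- spearman_test(x, y, n_perm = 4999, seed = 2)
  ct <- cor.test(x, y, method = "spearman")
  expect_equal(sp2$rho, unname(ct$estimate), tolerance = 1e-12)
  # monotone-transform invariance
  sp3 <- spearman_test(exp(x), y^3 + 100, n_perm = 4999, seed = 2)
  expect_equal(sp3$rho, sp2$rho, tolerance = 1e-12)
  expect_identical(sp3$p_value, sp2$p_value)
  # perfect monotone association
  expect_equal(spearman_test(1:10, log(1:10 + 2), n_perm = 99)$rho, 1)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  # p floors at 1/(n_perm+1)
  expect_gte(spearman_test(1:10, 1:10, n_perm = 99)$p_value, 1 / 100)
})

test_that("t-approximation reproduces the magnitude of published p-values", {
  # a 15-point rank correlation near 0.83 sits at the 1e-4 order by the
  # t approximation; build the permutation explicitly (sum d^2 = 90)
  y <- 1:15
  swap <- function(v, a, b) { v[c(a, b)] <- v[c(b, a)]; v }
  for (pr in list(c(1, 4), c(5, 8), c(9, 12), c(10, 14), c(2, 3), c(6, 7)))
    y <- swap(y, pr[1], pr[2])
  sp <- spearman_test(1:15, y, n_perm = 999, seed = 1)
  expect_equal(sp$rho, 1 - 6 * 90 / (15 * (15^2 - 1)), tolerance = 1e-12)
  expect_lt(sp$p_t, 1e-3)
  expect_gt(sp$p_t, 1e-5)
})

test_that("per-stratum delta recovers the gene-level selection gradient", {
  # genes span |gamma_L| 0..30; strata ordered by true constraint should show
  # increasing delta and positive Spearman correlation with the stratifier
  s_g <- seq(0, 30, length.out = 90) / (4 * 6000)
  cfg <- small_sim(seed = 17, n_genes = 90, s = s_g, mu = 2e-6,
                   n_chrom = 6, chrom_length = 4e6)
  ds <- generate_dataset(cfg, scores = TRUE)
  cp <- suppressMessages(gene_constraint_proportion(ds$genes, ds$scores))
  strat <- equal_count_bins(cp$constraint_prop, cp$gene_id, bin_size = 15)
  st <- suppressMessages(strata_delta(
    ds$variants, setNames(strat, cp$gene_id),
    setNames(cp$constraint_prop, cp$gene_id),
    ds$gene_sites, "large", "small"))
  expect_equal(nrow(st), 6L)
  expect_equal(sum(st$n_genes), 90L)
  ok <- is.finite(st$delta_percent)
  expect_gte(sum(ok), 5)
  sp <- spearman_test(st$mean_value[ok], st$delta_percent[ok], n_perm = 999)
  expect_gt(sp$rho, 0)
  # theoretical per-stratum deltas are monotone in the stratifier
  d_theory <- vapply(sort(unique(strat)), function(k) {
    gi <- match(cp$gene_id[strat == k], ds$gene_sites$gene_id)
    theoretical_delta(cfg$Ne_L, cfg$Ne_S, s_g[gi],
                      weights = ds$gene_sites$n_sites[gi])
  }, numeric(1))
  expect_true(all(diff(d_theory) > -0.02))
})

test_that("stratum delta is 0 for identical populations and stable under pooling", {
  cfg <- small_sim(seed = 19, n_genes = 30, mu = 2e-6)
  ds <- generate_dataset(cfg, scores = FALSE)
  v <- ds$variants
  v$j_small <- v$j_large; v$n_small <- v$n_large
  ids <- ds$gene_sites$gene_id
  strat <- setNames(rep(1:2, each = 15), ids)
  vals <- setNames(seq_along(ids), ids)
  st <- suppressMessages(strata_delta(v, strat, vals, ds$gene_sites,
                                      "large", "small"))
  expect_true(all(abs(st$delta[is.finite(st$delta)]) < 1e-12))
  # merging all genes into one stratum leaves a single pooled delta defined
  st1 <- suppressMessages(strata_delta(v, setNames(rep(1L, 30), ids), vals,
                                       ds$gene_sites, "large", "small"))
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$delta[1], 0, tolerance = 1e-12)
})
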