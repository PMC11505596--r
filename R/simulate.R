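## Two-population synthetic SNV datasets with the statistical structure the
## excess-heterozygosity analysis assumes: neutral classes (intron,
## intergenic, synonymous) at gamma = 0, nonsynonymous sites of gene g at
## gamma_g = -4 * Ne * s_g, constraint scores and expression correlated with
## |gamma|, and closed-form oracles for the expected diversities.
##
## Populations are simulated independently at equilibrium (no shared
## ancestry, migration or demography): the excess statistic delta compares
## per-population equilibrium diversities only, so divergence structure is
## irrelevant to its definition — but see the methods vignette for what this
## does and does not emulate.

#' Simulation configuration
#'
#' Defaults describe a desk-scale caricature of the chimpanzee comparison:
#' a large population of Ne 60,000 against a small one of Ne 10,000
#' (the troglodytes/verus contrast), mammalian-scale mutation rate, 10
#' diploid samples per population, and ~1e6 neutral / ~1.5e5 nonsynonymous
#' callable sites spread over 8 chromosomes of 7 Mb so that 1-Mb bootstrap
#' blocks carry realistic site mixtures and the intergenic windows sit at
#' least 1 Mb from any gene (usable as a distal neutral reference).
#'
#' @param Ne_L,Ne_S effective sizes (Ne_L > Ne_S > 0).
#' @param mu per-site per-generation mutation rate; 4*Ne*mu must stay below
#'   0.1 (infinite-sites regime).
#' @param s heterozygous selection coefficient of nonsynonymous sites
#'   (fitness 1, 1-s, 1-2s); scalar, or a vector of length `n_genes` for
#'   gene-level selection intensities. Default puts gamma_L = -10.
#' @param n_diploids diploid samples per population (default 10).
#' @param n_chrom,chrom_length genome layout (default 8 x 7 Mb).
#' @param n_genes,cds_len,intron_len genes and their structure; `cds_len`
#'   must be a multiple of 3 (default 200 genes, 999 bp CDS, 2500 bp
#'   intron).
#' @param intergenic_len callable intergenic window per chromosome, placed
#'   at the chromosome end, at least 1 Mb downstream of the last gene when
#'   the chromosome allows (default 62,500 bp).
#' @param score_slope,score_sd synthetic per-site conservation score model:
#'   score = score_slope * log(1 + |gamma_L|) + Normal(0, score_sd).
#' @param expr_intercept,expr_slope,expr_sd synthetic log-expression model:
#'   expr = expr_intercept + expr_slope * log(1 + |gamma_L|) +
#'   Normal(0, expr_sd) (positive slope: highly expressed genes are more
#'   constrained).
#' @param missing_rate per-(site, individual) genotype missingness
#'   probability (default 0).
#' @param grid_n frequency-grid resolution for [sample_sfs()].
#' @param seed RNG seed (default 1; logged in the truth record).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(Ne_L = 60000, Ne_S = 10000, mu = 1.25e-8,
                       s = 10 / (4 * 60000),
                       n_diploids = 10,
                       n_chrom = 8, chrom_length = 7e6,
                       n_genes = 200, cds_len = 999, intron_len = 2500,
                       intergenic_len = 62500,
                       score_slope = 1, score_sd = 1,
                       expr_intercept = 4, expr_slope = 1, expr_sd = 0.5,
                       missing_rate = 0, grid_n = 1e4, seed = 1) {
  stopifnot(Ne_L > 0, Ne_S > 0, mu > 0, all(s >= 0),
            n_diploids >= 2, n_chrom >= 1, chrom_length > 0,
            n_genes >= 1, cds_len > 0, intron_len >= 0, intergenic_len >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (cds_len %% 3 != 0) stop("cds_len must be a multiple of 3")
  if (!length(s) %in% c(1L, n_genes))
    stop("s must be scalar or length n_genes")
  for (Ne in c(Ne_L, Ne_S)) {
    if (4 * Ne * mu >= 0.1)
      stop("4*Ne*mu = ", 4 * Ne * mu, " violates the infinite-sites regime (< 0.1)")
    if (n_diploids > Ne) stop("sample size exceeds Ne")
  }
  structure(as.list(environment()), class = "sim_config")
}

# deterministic genome layout: gene anchors and intergenic windows
sim_layout <- function(cfg) {
  n_per <- ceiling(cfg$n_genes / cfg$n_chrom)
  chrom_i <- rep(seq_len(cfg$n_chrom), each = n_per)[seq_len(cfg$n_genes)]
  within_i <- unlist(lapply(seq_len(cfg$n_chrom),
                            function(c) seq_len(sum(chrom_i == c))))
  span <- cfg$cds_len + cfg$intron_len
  margin <- max(1, round(0.02 * cfg$chrom_length))
  distal_gap <- min(1e6, round(0.15 * cfg$chrom_length))
  avail <- cfg$chrom_length - cfg$intergenic_len - distal_gap - margin - span
  if (avail < 0) stop("chrom_length too short for the gene layout")
  spacing <- if (n_per > 1) max(span + 1, floor(avail / (n_per - 1))) else 0
  if (n_per > 1 && margin + (n_per - 1) * spacing + span >
      cfg$chrom_length - cfg$intergenic_len - distal_gap)
    stop("chrom_length too short for ", n_per, " genes per chromosome")
  anchor0 <- margin + (within_i - 1) * spacing
  data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = paste0("chr", chrom_i),
    cds_start0 = anchor0,
    cds_end0 = anchor0 + cfg$cds_len,
    intron_start0 = anchor0 + cfg$cds_len,
    intron_end0 = anchor0 + cfg$cds_len + cfg$intron_len,
    stringsAsFactors = FALSE)
}

# draw sites of one class for one population; gene weights pick the gene,
# position is uniform within the gene's interval
draw_sites <- function(freqs, start0, len, weight, gene_ids, chroms) {
  k <- length(freqs)
  if (k == 0)
    return(data.table(chrom = character(), pos0 = integer(),
                      gene_id = character(), q = numeric()))
  gi <- sample.int(length(start0), k, replace = TRUE, prob = weight)
  pos0 <- start0[gi] + floor(runif(k) * len[gi])
  data.table(chrom = chroms[gi], pos0 = as.integer(pos0),
             gene_id = gene_ids[gi], q = freqs)
}

#' Generate a synthetic two-population SNV dataset
#'
#' For each population independently, segregating sites are drawn from the
#' diffusion frequency spectrum ([sample_sfs()]): neutral classes (intron,
#' intergenic, synonymous) at gamma = 0 and nonsynonymous sites of gene g at
#' gamma_g = -4 * Ne * s_g. Sample alt-allele counts are binomial draws
#' j ~ Binomial(2 * n_diploids, q) (the Hardy-Weinberg sampling distribution
#' of the allele count). Sites segregating in one population are absent
#' (j = 0) in the other — independent equilibrium populations under infinite
#' sites. Per-gene NG86 site counts come from randomly drawn stop-free CDS
#' sequences; per-site conservation scores and per-gene expression follow
#' the config's linear-in-log(1+|gamma|) models.
#'
#' @param cfg a [sim_config()].
#' @param scores generate the per-CDS-position score track (default TRUE;
#'   switch off to save time when constraint stratification is not needed).
#' @return list: `variants` (variant table with class, gene_id, effect and
#'   per-population counts), `map` ([site_class_map()] with NG86 L
#'   overrides), `genes` (feature table), `gene_sites` (gene_id, n_sites,
#'   s_sites, cds_len, intron_len), `scores` (score_track or NULL),
#'   `expression` (named vector), `truth` (gammas, thetas, theoretical
#'   delta, seed), `config`.
#' @export
generate_dataset <- function(cfg, scores = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lay <- sim_layout(cfg)
  n_g <- cfg$n_genes
  s_g <- if (length(cfg$s) == 1L) rep(cfg$s, n_g) else cfg$s

  # per-gene NG86 site counts from random stop-free CDS
  ng <- t(vapply(seq_len(n_g), function(i)
    ng86_site_counts(random_cds(cfg$cds_len %/% 3L)), numeric(2)))
  gene_sites <- data.frame(gene_id = lay$gene_id,
                           n_sites = ng[, "N"], s_sites = ng[, "S"],
                           cds_len = cfg$cds_len,
                           intron_len = cfg$intron_len,
                           stringsAsFactors = FALSE)

  # intergenic windows at chromosome ends
  ig <- data.frame(chrom = paste0("chr", seq_len(cfg$n_chrom)),
                   start0 = cfg$chrom_length - cfg$intergenic_len,
                   end0 = cfg$chrom_length)

  pops <- c("large", "small")
  Ne <- c(large = cfg$Ne_L, small = cfg$Ne_S)
  theta <- 4 * Ne * cfg$mu
  per_pop <- list()
  for (p in pops) {
    th <- theta[[p]]
    parts <- list()
    # intron (neutral)
    fr <- sample_sfs(0, th, n_g * cfg$intron_len, Ne[[p]], cfg$grid_n)
    d <- draw_sites(fr, lay$intron_start0, rep(cfg$intron_len, n_g),
                    rep(cfg$intron_len, n_g), lay$gene_id, lay$chrom)
    d[, class := "intron"]
    parts[[length(parts) + 1L]] <- d
    # intergenic (neutral)
    if (cfg$intergenic_len > 0) {
      fr <- sample_sfs(0, th, nrow(ig) * cfg$intergenic_len, Ne[[p]], cfg$grid_n)
      d <- draw_sites(fr, ig$start0, ig$end0 - ig$start0,
                      ig$end0 - ig$start0, rep(NA_character_, nrow(ig)),
                      ig$chrom)
      d[, class := "intergenic"]
      parts[[length(parts) + 1L]] <- d
    }
    # synonymous (neutral), weighted by per-gene S counts
    fr <- sample_sfs(0, th, sum(gene_sites$s_sites), Ne[[p]], cfg$grid_n)
    d <- draw_sites(fr, lay$cds_start0, rep(cfg$cds_len, n_g),
                    gene_sites$s_sites, lay$gene_id, lay$chrom)
    d[, class := "synonymous"]
    parts[[length(parts) + 1L]] <- d
    # nonsynonymous: one spectrum per distinct selection coefficient
    gam <- -4 * Ne[[p]] * s_g
    for (g0 in unique(gam)) {
      gi <- which(gam == g0)
      fr <- sample_sfs(g0, th, sum(gene_sites$n_sites[gi]), Ne[[p]], cfg$grid_n)
      d <- draw_sites(fr, lay$cds_start0[gi], rep(cfg$cds_len, length(gi)),
                      gene_sites$n_sites[gi], lay$gene_id[gi], lay$chrom[gi])
      d[, class := "nonsynonymous"]
      parts[[length(parts) + 1L]] <- d
    }
    pp <- rbindlist(parts)
    # sample the population frequency
    nd <- cfg$n_diploids
    miss <- if (cfg$missing_rate > 0)
      rbinom(nrow(pp), nd, cfg$missing_rate) else integer(nrow(pp))
    pp$n <- 2L * (nd - miss)
    pp$j <- rbinom(nrow(pp), pp$n, pp$q)
    pp <- pp[pp$j > 0]          # invisible in a variant call set otherwise
    pp$pop <- p
    per_pop[[p]] <- pp
  }
  v <- rbindlist(per_pop)

  # resolve position collisions (infinite sites: every variant distinct);
  # redraw within the same gene/window, then drop any stragglers
  interval_of <- function(rows) {
    out <- data.table(start0 = integer(nrow(rows)), len = integer(nrow(rows)))
    icds <- rows$class %in% c("synonymous", "nonsynonymous")
    gi <- match(rows$gene_id, lay$gene_id)
    out$start0[icds] <- lay$cds_start0[gi[icds]]
    out$len[icds] <- cfg$cds_len
    iint <- rows$class == "intron"
    out$start0[iint] <- lay$intron_start0[gi[iint]]
    out$len[iint] <- cfg$intron_len
    iig <- rows$class == "intergenic"
    wi <- match(rows$chrom, ig$chrom)
    out$start0[iig] <- ig$start0[wi[iig]]
    out$len[iig] <- cfg$intergenic_len
    out
  }
  for (it in 1:30) {
    dup <- duplicated(v, by = c("chrom", "pos0"))
    if (!any(dup)) break
    iv <- interval_of(v[dup])
    v$pos0[dup] <- as.integer(iv$start0 + floor(runif(sum(dup)) * iv$len))
  }
  dup <- duplicated(v, by = c("chrom", "pos0"))
  if (any(dup)) {
    message("dropping ", sum(dup), " unresolvable position collision(s)")
    v <- v[!dup]
  }

  # wide table with per-population counts; absent population: j = 0
  nfull <- 2L * cfg$n_diploids
  v[, pos := pos0 + 1L]
  wide <- v[, .(chrom, pos, class, gene_id, pop, j, n)]
  for (p in pops) {
    wide[[paste0("j_", p)]] <- ifelse(wide$pop == p, wide$j, 0L)
    wide[[paste0("n_", p)]] <- ifelse(wide$pop == p, wide$n, nfull)
  }
  wide[, c("pop", "j", "n") := NULL]
  # alleles: ref then a distinct alt
  wide$ref <- sample(BASES, nrow(wide), replace = TRUE)
  shift <- sample.int(3, nrow(wide), replace = TRUE)
  wide$alt <- BASES[(match(wide$ref, BASES) - 1L + shift) %% 4L + 1L]
  wide$effect <- ifelse(wide$class == "nonsynonymous", "missense_variant",
                 ifelse(wide$class == "synonymous", "synonymous_variant",
                        NA_character_))
  setorder(wide, chrom, pos)
  setcolorder(wide, c("chrom", "pos", "ref", "alt", "effect", "class",
                      "gene_id"))
  variants <- wide

  # class map with NG86 L overrides for the coding classes
  cds_gr <- GRanges(lay$chrom, IRanges(lay$cds_start0 + 1, lay$cds_end0))
  intron_gr <- GRanges(lay$chrom, IRanges(lay$intron_start0 + 1, lay$intron_end0))
  ig_gr <- GRanges(ig$chrom, IRanges(ig$start0 + 1, ig$end0))
  map <- site_class_map(
    list(exome = cds_gr, intron = intron_gr, intergenic = ig_gr),
    L = c(synonymous = sum(gene_sites$s_sites),
          nonsynonymous = sum(gene_sites$n_sites)))

  genes <- rbind(
    data.frame(gene_id = lay$gene_id, chrom = lay$chrom,
               start0 = lay$cds_start0, end0 = lay$cds_end0,
               feature = "cds", stringsAsFactors = FALSE),
    data.frame(gene_id = lay$gene_id, chrom = lay$chrom,
               start0 = lay$intron_start0, end0 = lay$intron_end0,
               feature = "intron", stringsAsFactors = FALSE))

  gamma_L <- -4 * cfg$Ne_L * s_g
  loggam <- log(1 + abs(gamma_L))
  score_track <- NULL
  if (scores) {
    npos <- n_g * cfg$cds_len
    sc <- rep(cfg$score_slope * loggam, each = cfg$cds_len) +
      rnorm(npos, sd = cfg$score_sd)
    score_track <- data.table(
      chrom = rep(lay$chrom, each = cfg$cds_len),
      start0 = unlist(lapply(seq_len(n_g), function(i)
        seq(lay$cds_start0[i], lay$cds_end0[i] - 1L))),
      score = round(sc, 3))
    score_track[, end0 := start0 + 1L]
    setcolorder(score_track, c("chrom", "start0", "end0", "score"))
    class(score_track) <- c("score_track", class(score_track))
  }
  expression <- stats::setNames(
    cfg$expr_intercept + cfg$expr_slope * loggam +
      rnorm(n_g, sd = cfg$expr_sd),
    lay$gene_id)

  truth <- list(
    seed = cfg$seed,
    s = s_g,
    gamma_large = gamma_L,
    gamma_small = -4 * cfg$Ne_S * s_g,
    theta_large = 4 * cfg$Ne_L * cfg$mu,
    theta_small = 4 * cfg$Ne_S * cfg$mu,
    delta_nonsyn_intron = theoretical_delta(cfg$Ne_L, cfg$Ne_S, s_g,
                                            weights = gene_sites$n_sites))
  list(variants = variants, map = map, genes = genes,
       gene_sites = gene_sites, scores = score_track,
       expression = expression, truth = truth, config = cfg)
}

#' Write a generated dataset to standard files
#'
#' Emits VCF (two population sample sets), per-class BED, a per-class
#' site-count TSV, gene feature and site-count TSVs, the per-position score
#' track (bedGraph), the expression TSV and a truth JSON.
#'
#' @param ds a [generate_dataset()] result.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  files <- c(vcf = fp("variants.vcf"),
             exome = fp("exome.bed"), intron = fp("intron.bed"),
             intergenic = fp("intergenic.bed"),
             site_counts = fp("site_counts.tsv"),
             genes = fp("genes.tsv"), gene_sites = fp("gene_sites.tsv"),
             expression = fp("expression.tsv"),
             truth = fp("truth.json"))
  write_vcf(ds$variants, files[["vcf"]],
            n_diploids = c(large = ds$config$n_diploids,
                           small = ds$config$n_diploids))
  for (cl in c("exome", "intron", "intergenic"))
    write_bed(ds$map, cl, files[[cl]])
  L <- vapply(c("intron", "intergenic", "synonymous", "nonsynonymous", "exome"),
              function(cl) class_L(ds$map, cl), numeric(1))
  fwrite(data.table(class = names(L), L = L), files[["site_counts"]], sep = "\t")
  fwrite(as.data.table(ds$genes), files[["genes"]], sep = "\t")
  fwrite(as.data.table(ds$gene_sites), files[["gene_sites"]], sep = "\t")
  fwrite(data.table(gene_id = names(ds$expression),
                    expression = round(unname(ds$expression), 4)),
         files[["expression"]], sep = "\t")
  if (!is.null(ds$scores)) {
    files[["scores"]] <- fp("scores.bedgraph")
    fwrite(as.data.table(ds$scores), files[["scores"]], sep = "\t",
           col.names = FALSE)
  }
  jsonlite::write_json(ds$truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  files
}
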