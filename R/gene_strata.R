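## Gene stratification by selective constraint (proportion of PhyloP-style
## conserved sites) or expression, per-stratum diversities and delta, and the
## Spearman trend test.

#' Per-gene proportion of constrained sites
#'
#' Fraction of a gene's CDS positions whose conservation score is strictly
#' greater than `threshold` (default 2.0, the conventional PhyloP cut-off
#' for constraint). Positions without a score stay in the denominator and
#' count as non-constrained; the aggregate score coverage is reported via
#' `message()`.
#'
#' @param genes gene feature table (gene_id, chrom, start0, end0, feature);
#'   rows with `feature == region` define the positions scored.
#' @param scores a [read_scores()] track.
#' @param threshold constraint cut-off (strict inequality; default 2.0).
#' @param region which feature rows to score (default "cds"; the diversity
#'   being stratified is nonsynonymous, so CDS is the natural span).
#' @return data.frame: gene_id, length, n_constrained, constraint_prop.
#' @export
gene_constraint_proportion <- function(genes, scores, threshold = 2.0,
                                       region = "cds") {
  g <- as.data.table(genes)[feature == region]
  if (nrow(g) == 0) stop("no '", region, "' features in gene table")
  glen <- g[, .(length = sum(end0 - start0)), by = gene_id]
  if (any(glen$length <= 0)) stop("zero-length CDS for gene ",
                                  glen$gene_id[glen$length <= 0][1])
  ggr <- GRanges(g$chrom, IRanges(g$start0 + 1, g$end0))
  sgr <- GRanges(scores$chrom, IRanges(scores$start0 + 1, scores$end0))
  ov <- GenomicRanges::findOverlaps(ggr, sgr)
  covered <- numeric(nrow(glen)); constrained <- numeric(nrow(glen))
  if (length(ov)) {
    pi_ <- GenomicRanges::pintersect(ggr[queryHits(ov)], sgr[subjectHits(ov)])
    w <- GenomicRanges::width(pi_)
    gid <- g$gene_id[queryHits(ov)]
    hi <- scores$score[subjectHits(ov)] > threshold
    cov_by <- rowsum(w, gid)
    con_by <- rowsum(w * hi, gid)
    covered[match(rownames(cov_by), glen$gene_id)] <- cov_by[, 1]
    constrained[match(rownames(con_by), glen$gene_id)] <- con_by[, 1]
  }
  frac_cov <- sum(covered) / sum(glen$length)
  message(sprintf("score coverage of %s positions: %.1f%%", region,
                  100 * frac_cov))
  data.frame(gene_id = glen$gene_id, length = glen$length,
             n_constrained = constrained,
             constraint_prop = constrained / glen$length,
             stringsAsFactors = FALSE)
}

#' Equal-count stratification
#'
#' Sorts genes ascending by the stratifier (ties broken by id for
#' determinism) and cuts consecutive chunks of `bin_size`. A remainder
#' smaller than half a bin merges into the final full chunk; a larger
#' remainder forms its own stratum. (14,870 genes at bin_size 1000 give 15
#' strata; 9,089 give 9.)
#'
#' @param values numeric stratifier per gene.
#' @param ids gene ids (tie-break and names; default seq_along).
#' @param bin_size genes per stratum (default 1000; >= 2).
#' @return integer vector of stratum ordinals (1 = lowest stratifier),
#'   aligned with the input order.
#' @export
equal_count_bins <- function(values, ids = NULL, bin_size = 1000) {
  if (bin_size < 2) stop("bin_size must be >= 2")
  n <- length(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n < bin_size) {
    warning("fewer genes (", n, ") than one bin: single stratum")
    return(rep(1L, n))
  }
  ord <- order(values, ids)
  k_full <- n %/% bin_size
  rem <- n %% bin_size
  sizes <- rep(bin_size, k_full)
  if (rem > 0) {
    if (rem >= bin_size / 2) sizes <- c(sizes, rem)
    else sizes[k_full] <- sizes[k_full] + rem
  }
  stratum <- integer(n)
  stratum[ord] <- rep(seq_along(sizes), sizes)
  stratum
}

#' Per-stratum diversities and excess fraction
#'
#' For each stratum of genes, nonsynonymous pi is the sum of site
#' heterozygosities over nonsynonymous SNVs in the stratum's genes divided by
#' the stratum's summed NG86 nonsynonymous site count, and intron pi likewise
#' over the stratum's introns. delta% then follows from the four per-stratum
#' diversities; with `neutral = "global"` the genome-wide intron diversities
#' replace the per-stratum ones. A stratum with zero neutral diversity in
#' either population is reported as missing (NA), never fabricated.
#'
#' @param variants variant table with `class` and `gene_id` assigned.
#' @param stratum named integer vector: gene_id -> stratum ordinal (from
#'   [equal_count_bins()]).
#' @param strat_values named numeric: gene_id -> stratifier value (for the
#'   reported stratum means).
#' @param gene_sites data.frame with gene_id, n_sites (NG86 nonsynonymous),
#'   s_sites, intron_len.
#' @param large_pop,small_pop population ids.
#' @param neutral `"stratum"` (default) or `"global"` intron reference.
#' @return data.frame, one row per stratum: stratum, n_genes, mean_value,
#'   pi_N_large, pi_N_small, pi_I_large, pi_I_small, delta, delta_percent.
#' @export
strata_delta <- function(variants, stratum, strat_values, gene_sites,
                         large_pop, small_pop, neutral = c("stratum", "global")) {
  neutral <- match.arg(neutral)
  v <- as.data.table(variants)
  gs <- as.data.table(gene_sites)
  gids <- names(stratum)
  stopifnot(!is.null(gids), all(gids %in% gs$gene_id))
  strat <- data.table(gene_id = gids, stratum = as.integer(stratum),
                      value = as.numeric(strat_values[gids]))
  gs <- merge(gs, strat, by = "gene_id")
  persite <- function(pop, cls) {
    jn <- v[class == cls & gene_id %in% gids]
    if (nrow(jn) == 0) return(data.table(stratum = integer(), num = numeric()))
    jn <- merge(jn, strat[, .(gene_id, stratum)], by = "gene_id")
    n <- jn[[paste0("n_", pop)]]; j <- jn[[paste0("j_", pop)]]
    jn <- jn[n >= 2]
    jn$sp <- site_pi(j[n >= 2], n[n >= 2])
    jn[, .(num = sum(sp)), by = stratum]
  }
  agg <- gs[, .(n_genes = .N, mean_value = mean(value),
                L_N = sum(n_sites), L_I = sum(intron_len)), by = stratum]
  setorder(agg, stratum)
  for (pop in c(large_pop, small_pop)) {
    for (cls in c("nonsynonymous", "intron")) {
      nm <- paste0("num_", substr(cls, 1, 1), "_", pop)
      ps <- persite(pop, cls)
      agg[[nm]] <- ps$num[match(agg$stratum, ps$stratum)]
      agg[[nm]][is.na(agg[[nm]])] <- 0
    }
  }
  out <- as.data.frame(agg)
  out$pi_N_large <- out[[paste0("num_n_", large_pop)]] / out$L_N
  out$pi_N_small <- out[[paste0("num_n_", small_pop)]] / out$L_N
  out$pi_I_large <- out[[paste0("num_i_", large_pop)]] / out$L_I
  out$pi_I_small <- out[[paste0("num_i_", small_pop)]] / out$L_I
  if (neutral == "global") {
    out$pi_I_large <- sum(out[[paste0("num_i_", large_pop)]]) / sum(out$L_I)
    out$pi_I_small <- sum(out[[paste0("num_i_", small_pop)]]) / sum(out$L_I)
  }
  ok <- out$pi_I_large > 0 & out$pi_I_small > 0 & out$pi_N_small > 0
  if (any(!ok))
    message(sum(!ok), " stratum/strata with zero neutral or constrained ",
            "diversity reported as missing")
  out$delta <- ifelse(ok,
    1 - (out$pi_N_large / out$pi_I_large) / (out$pi_N_small / out$pi_I_small),
    NA_real_)
  out$delta_percent <- 100 * out$delta
  keep <- c("stratum", "n_genes", "mean_value",
            "pi_N_large", "pi_N_small", "pi_I_large", "pi_I_small",
            "delta", "delta_percent")
  out[, keep]
}

#' Spearman rank correlation with a permutation p-value
#'
#' rho is the Pearson correlation of average ranks (ties averaged). The
#' two-sided p-value comes from `n_perm` random permutations of y with the
#' add-one correction, so p >= 1/(n_perm + 1); the usual t-approximation
#' (t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df) is reported alongside.
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param n_perm permutation count (default 99999).
#' @param seed RNG seed (default 1).
#' @return list of class `spearman_result`: rho, p_value (permutation),
#'   p_t (t-approximation), n, n_perm.
#' @export
spearman_test <- function(x, y, n_perm = 99999, seed = 1) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4 || length(y) != n) stop("need equal-length x, y with n >= 4")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant x or y: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)), numeric(1))
  p_perm <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p_t <- 2 * pt(-abs(tstat), df = n - 2)
  structure(list(rho = rho, p_value = p_perm, p_t = p_t, n = n,
                 n_perm = n_perm),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d); permutation p = %.3g (t-approx p = %.3g)\n",
              x$rho, x$n, x$p_value, x$p_t))
  invisible(x)
}
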