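## Per-site-class nucleotide diversity (Tajima's mean pairwise differences per
## site) and the 1-Mb block machinery used for bootstrap standard errors.
##
## Variant tables are data.frames with columns chrom, pos (1-based), ref, alt,
## class, gene_id and, per population <p>, the alt-allele count j_<p> and the
## called-chromosome count n_<p>.

#' Population ids carried by a variant table
#' @param variants a variant table (see [read_vcf()]).
#' @return character vector of population ids.
#' @export
populations_of <- function(variants) {
  nm <- names(variants)
  sub("^j_", "", grep("^j_", nm, value = TRUE))
}

#' Per-site heterozygosity (Tajima)
#'
#' Fraction of differing chromosome pairs at one biallelic site:
#' \eqn{2 j (n-j) / (n (n-1))} for alt-allele count j among n called
#' chromosomes. Vectorised.
#'
#' @param j alt-allele count(s), 0 <= j <= n.
#' @param n called chromosome count(s), n >= 2.
#' @return per-site heterozygosity in \[0, 1\].
#' @examples
#' site_pi(1, 4)  # 0.5: 3 of the 6 chromosome pairs differ
#' @export
site_pi <- function(j, n) {
  if (any(n < 2)) stop("site_pi requires n >= 2 called chromosomes")
  if (any(j < 0) || any(j > n)) stop("need 0 <= j <= n")
  2 * j * (n - j) / (n * (n - 1))
}

#' Drop sites with too few called chromosomes
#'
#' The per-site estimator's variance explodes at tiny n, so sites where any
#' population has fewer than `min_n` called chromosomes are removed before
#' diversity estimation (missing genotypes reduce n per site rather than
#' dropping the site outright at read time).
#'
#' @param variants variant table.
#' @param min_n minimum called chromosomes required in every population
#'   (default 4).
#' @return filtered variant table.
#' @export
filter_min_called <- function(variants, min_n = 4) {
  pops <- populations_of(variants)
  keep <- rep(TRUE, nrow(variants))
  for (p in pops) keep <- keep & variants[[paste0("n_", p)]] >= min_n
  variants[keep, , drop = FALSE]
}

classes_matching <- function(class_col, site_class) {
  if (site_class == "exome") {
    # exome = synonymous U nonsynonymous (plus unannotated coding)
    class_col %in% c("exome", "synonymous", "nonsynonymous")
  } else if (site_class == "intergenic") {
    # the distal subset is still intergenic
    class_col %in% c("intergenic", "intergenic_distal")
  } else {
    class_col == site_class
  }
}

#' Diversity of one site class in one population
#'
#' \eqn{\pi = \sum \mathrm{site\_pi} / L_c} over the SNVs of the class;
#' monomorphic callable sites enter only through the denominator
#' \eqn{L_c}. The class "exome" is the union of synonymous and nonsynonymous
#' (plus unannotated coding) sites.
#'
#' @param variants variant table with `class` assigned.
#' @param site_class class name.
#' @param L_c callable-site total for the class (> 0; fractional permitted for
#'   NG86 synonymous/nonsynonymous site counts).
#' @param population population id present in the table.
#' @return one-row data.frame: population, class, n_snvs, L, pi, se (NA until
#'   bootstrapped).
#' @export
class_pi <- function(variants, site_class, L_c, population) {
  if (!is.numeric(L_c) || length(L_c) != 1L || !is.finite(L_c) || L_c <= 0)
    stop("L_c must be a single positive number")
  jcol <- paste0("j_", population)
  ncol_ <- paste0("n_", population)
  if (!jcol %in% names(variants))
    stop("population '", population, "' not present in variant table")
  sel <- classes_matching(variants$class, site_class)
  j <- variants[[jcol]][sel]
  n <- variants[[ncol_]][sel]
  ok <- n >= 2
  pi_sum <- if (any(ok)) sum(site_pi(j[ok], n[ok])) else 0
  data.frame(population = population, class = site_class,
             n_snvs = sum(ok), L = L_c, pi = pi_sum / L_c, se = NA_real_,
             stringsAsFactors = FALSE)
}

#' Diversity table for all populations and classes
#'
#' @param variants variant table with classes assigned.
#' @param map a [site_class_map()] supplying the denominators L_c.
#' @param classes classes to report (default: all classes in the map plus
#'   "exome" when synonymous and nonsynonymous are present).
#' @return data.frame of [class_pi()] rows.
#' @export
diversity_table <- function(variants, map, classes = NULL) {
  stopifnot(inherits(map, "site_class_map"))
  if (is.null(classes)) {
    classes <- names(map$L)
    if (all(c("synonymous", "nonsynonymous") %in% classes) &&
        !"exome" %in% classes)
      classes <- c(classes, "exome")
  }
  pops <- populations_of(variants)
  out <- list()
  for (p in pops) for (cl in classes) {
    out[[length(out) + 1L]] <- class_pi(variants, cl, class_L(map, cl), p)
  }
  do.call(rbind, out)
}

#' Partition variants and class lengths into genomic blocks
#'
#' A variant with 1-based position pos falls in block ordinal
#' \eqn{\lfloor (pos-1)/\mathrm{block\_size} \rfloor} of its chromosome;
#' class interval lengths are apportioned to blocks by intersection. The
#' default block size of 1 Mb matches the resampling unit used for the
#' bootstrap standard errors.
#'
#' @param variants variant table with classes assigned.
#' @param map a [site_class_map()].
#' @param block_size block length in bp (default 1e6).
#' @return an object of class `block_index`: `$blocks` (chrom, ordinal),
#'   `$lengths` (block x class matrix of callable bp), `$block_of` (block row
#'   index per variant), `$variants`, `$classes`.
#' @export
partition_blocks <- function(variants, map, block_size = 1e6) {
  stopifnot(inherits(map, "site_class_map"), block_size > 0)
  classes <- names(map$intervals)
  # block spans per class interval (0-based half-open internally here)
  pieces <- list()
  for (cl in classes) {
    gr <- map$intervals[[cl]]
    if (length(gr) == 0) next
    s0 <- GenomicRanges::start(gr) - 1L
    e0 <- GenomicRanges::end(gr)
    b0 <- s0 %/% block_size
    b1 <- (e0 - 1L) %/% block_size
    nrep <- b1 - b0 + 1L
    idx <- rep(seq_along(gr), nrep)
    ord <- unlist(lapply(seq_along(gr), function(i) seq(b0[i], b1[i])))
    lo <- pmax(s0[idx], ord * block_size)
    hi <- pmin(e0[idx], (ord + 1) * block_size)
    pieces[[cl]] <- data.table(
      chrom = as.character(GenomicRanges::seqnames(gr))[idx],
      ordinal = ord, class = cl, len = hi - lo)
  }
  lens <- rbindlist(pieces)
  vb <- data.table(chrom = as.character(variants$chrom),
                   ordinal = (variants$pos - 1L) %/% block_size)
  blocks <- unique(rbind(lens[, .(chrom, ordinal)], vb))
  setorder(blocks, chrom, ordinal)
  blocks[, block := .I]
  lmat <- matrix(0, nrow = nrow(blocks), ncol = length(classes),
                 dimnames = list(NULL, classes))
  if (nrow(lens)) {
    lens <- merge(lens, blocks, by = c("chrom", "ordinal"))
    agg <- lens[, .(len = sum(len)), by = .(block, class)]
    lmat[cbind(agg$block, match(agg$class, classes))] <- agg$len
  }
  block_of <- merge(vb[, row := .I], blocks, by = c("chrom", "ordinal"),
                    sort = FALSE)[order(row), block]
  structure(list(blocks = as.data.frame(blocks),
                 lengths = lmat,
                 block_of = block_of,
                 variants = variants,
                 classes = classes,
                 block_size = block_size),
            class = "block_index")
}

#' @export
print.block_index <- function(x, ...) {
  cat("block_index:", nrow(x$blocks), "blocks of", format(x$block_size, big.mark = ","),
      "bp;", nrow(x$variants), "variants;", length(x$classes), "classes\n")
  invisible(x)
}

#' Block bootstrap over genomic windows
#'
#' Each replicate draws as many blocks as there are, with replacement, and
#' recomputes the statistic on the pooled resample; the standard error is the
#' standard deviation (denominator B-1) of the replicate values. The statistic
#' receives the integer vector of sampled block indices so that it can pool
#' per-block numerators and denominators before dividing (ratio of sums, not
#' mean of ratios). Replicates on which the statistic is undefined (NA/NaN,
#' e.g. a zero denominator) are dropped from the SE with a message; more than
#' 10% undefined is an error.
#'
#' @param blocks a `block_index` (or anything whose blocks the statistic can
#'   index) — only the number of blocks is used here.
#' @param statistic function(block_ids) -> single number.
#' @param B number of replicates (default 1000).
#' @param seed RNG seed (required for reproducibility; default 1).
#' @return list: `se`, `replicates` (length B, NA where undefined),
#'   `n_missing`.
#' @export
block_bootstrap <- function(blocks, statistic, B = 1000, seed = 1) {
  nb <- if (inherits(blocks, "block_index")) nrow(blocks$blocks) else as.integer(blocks)
  if (nb < 2) stop("block bootstrap needs at least 2 blocks")
  if (B < 2) stop("need B >= 2 replicates")
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(nb, nb, replace = TRUE)
    as.numeric(statistic(idx))
  }, numeric(1))
  bad <- !is.finite(reps)
  reps[bad] <- NA_real_
  if (sum(bad) > 0.1 * B)
    stop("statistic undefined on ", sum(bad), " of ", B, " bootstrap replicates")
  if (any(bad))
    message("block_bootstrap: ", sum(bad), " undefined replicate(s) excluded from SE")
  list(se = sd(reps[!bad]), replicates = reps, n_missing = sum(bad))
}

## Per-block sums of site_pi for (population, class) pairs, plus per-block
## class lengths: the building blocks for every bootstrapped ratio statistic.
block_sums <- function(bi, populations = NULL, classes = NULL) {
  v <- bi$variants
  if (is.null(populations)) populations <- populations_of(v)
  if (is.null(classes)) classes <- bi$classes
  nb <- nrow(bi$blocks)
  num <- array(0, dim = c(nb, length(classes), length(populations)),
               dimnames = list(NULL, classes, populations))
  cnt <- array(0L, dim = dim(num), dimnames = dimnames(num))
  for (p in populations) {
    j <- v[[paste0("j_", p)]]
    n <- v[[paste0("n_", p)]]
    ok <- n >= 2
    sp <- numeric(nrow(v))
    sp[ok] <- site_pi(j[ok], n[ok])
    for (cl in classes) {
      sel <- ok & classes_matching(v$class, cl)
      if (!any(sel)) next
      agg <- rowsum(sp[sel], group = bi$block_of[sel])
      num[as.integer(rownames(agg)), cl, p] <- agg[, 1]
      cnt[, cl, p] <- tabulate(bi$block_of[sel], nbins = nb)
    }
  }
  lens <- bi$lengths
  if ("exome" %in% classes && !"exome" %in% colnames(lens)) {
    ex <- rowSums(lens[, intersect(c("synonymous", "nonsynonymous"),
                                   colnames(lens)), drop = FALSE])
    lens <- cbind(lens, exome = ex)
  }
  list(num = num, cnt = cnt, len = lens[, classes, drop = FALSE])
}

#' Diversity table with block-bootstrap standard errors
#'
#' Point estimates use the full data; each bootstrap replicate resamples the
#' blocks once and recomputes every (population, class) pi from pooled sums,
#' so the replicate pis share the resample (preserving covariance for
#' downstream ratio statistics).
#'
#' @param bi a [partition_blocks()] result.
#' @param map a [site_class_map()] (denominators; L overrides respected —
#'   bootstrap denominators are rescaled accordingly).
#' @param classes classes to report (default as [diversity_table()]).
#' @param B,seed bootstrap replicates and seed.
#' @return data.frame with columns population, class, n_snvs, L, pi, se, B,
#'   seed.
#' @export
diversity_with_bootstrap <- function(bi, map, classes = NULL, B = 1000, seed = 1) {
  stopifnot(inherits(bi, "block_index"))
  if (is.null(classes)) {
    classes <- names(map$L)
    if (all(c("synonymous", "nonsynonymous") %in% classes) &&
        !"exome" %in% classes) classes <- c(classes, "exome")
  }
  pops <- populations_of(bi$variants)
  bs <- block_sums(bi, pops, classes)
  # map L may be an override (e.g. NG86 site counts) differing from interval
  # lengths: scale per-block lengths so they total the override.
  scale <- vapply(classes, function(cl) {
    tot <- sum(bs$len[, cl])
    L <- class_L(map, cl)
    if (tot > 0) L / tot else NA_real_
  }, numeric(1))
  out <- list()
  for (p in pops) for (cl in classes) {
    L <- class_L(map, cl)
    stat <- local({
      p0 <- p; cl0 <- cl
      function(idx) {
        den <- sum(bs$len[idx, cl0]) * scale[[cl0]]
        if (!is.finite(den) || den <= 0) return(NA_real_)
        sum(bs$num[idx, cl0, p0]) / den
      }
    })
    bb <- block_bootstrap(bi, stat, B = B, seed = seed)
    row <- class_pi(bi$variants, cl, L, p)
    row$se <- bb$se
    row$B <- B
    row$seed <- seed
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
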