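## Standard-format I/O and site-class assignment.
##
## Coordinate conventions: VCF positions are 1-based; BED and bedGraph files
## are 0-based half-open. Internally intervals live in GenomicRanges objects
## (1-based closed, the Bioconductor convention); conversion happens once at
## the file boundary.

KNOWN_CLASSES <- c("nonsynonymous", "synonymous", "intron", "intergenic",
                   "intergenic_distal", "exome")

bed_to_granges <- function(df, what = "BED") {
  if (ncol(df) < 3) stop(what, " needs at least 3 columns (chrom, start, end)")
  names(df)[1:3] <- c("chrom", "start0", "end0")
  if (!is.numeric(df$start0) || !is.numeric(df$end0))
    stop(what, " start/end must be numeric")
  bad <- which(df$end0 <= df$start0)
  if (length(bad))
    stop(what, " interval with end <= start at line ", bad[1])
  GRanges(df$chrom, IRanges(df$start0 + 1, df$end0))
}

granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr))
}

#' Construct a site-class map
#'
#' Holds, per site class, the genomic intervals (normalised: sorted and
#' merged) and the callable-site total L_c used as the diversity denominator.
#' L_c defaults to the summed interval length; explicit overrides (e.g.
#' fractional NG86 synonymous/nonsynonymous site counts) take precedence.
#' Classes given only an L override (no intervals of their own) borrow the
#' exome intervals for block apportionment, since synonymous and
#' nonsynonymous sites interleave within CDS.
#'
#' @param intervals named list of `GRanges` (or 3-column 0-based half-open
#'   data.frames), one per class.
#' @param L named numeric vector of L_c overrides (optional).
#' @return object of class `site_class_map` with elements `intervals`
#'   (named list of reduced GRanges) and `L` (named numeric).
#' @export
site_class_map <- function(intervals, L = NULL) {
  bad <- setdiff(c(names(intervals), names(L)), KNOWN_CLASSES)
  if (length(bad)) stop("unknown site class: ", paste(bad, collapse = ", "))
  ivs <- lapply(intervals, function(x) {
    gr <- if (inherits(x, "GRanges")) x else bed_to_granges(x)
    GenomicRanges::reduce(gr)
  })
  Lc <- vapply(ivs, function(gr) sum(as.numeric(GenomicRanges::width(gr))),
               numeric(1))
  if (!is.null(L)) {
    if (!is.numeric(L) || any(L < 0)) stop("L overrides must be non-negative")
    Lc[names(L)] <- L
  }
  # coding-site classes without their own intervals ride on the exome extent
  for (cl in intersect(c("synonymous", "nonsynonymous"), names(Lc))) {
    if (is.null(ivs[[cl]]) && !is.null(ivs[["exome"]])) ivs[[cl]] <- ivs[["exome"]]
  }
  structure(list(intervals = ivs, L = Lc), class = "site_class_map")
}

#' @export
print.site_class_map <- function(x, ...) {
  cat("site_class_map:\n")
  for (cl in names(x$L))
    cat(sprintf("  %-18s L = %s (%d interval(s))\n", cl,
                format(x$L[[cl]], big.mark = ","),
                length(x$intervals[[cl]])))
  invisible(x)
}

#' Callable-site total for a class
#' @param map a [site_class_map()].
#' @param site_class class name; "exome" falls back to the sum of the
#'   synonymous and nonsynonymous totals when not set directly.
#' @return L_c (numeric scalar).
#' @export
class_L <- function(map, site_class) {
  stopifnot(inherits(map, "site_class_map"))
  if (site_class %in% names(map$L)) return(map$L[[site_class]])
  if (site_class == "exome" &&
      all(c("synonymous", "nonsynonymous") %in% names(map$L)))
    return(map$L[["synonymous"]] + map$L[["nonsynonymous"]])
  stop("class absent from map: ", site_class)
}

#' Read per-class BED files into a site-class map
#'
#' @param bed_paths named list/vector of BED file paths, names are class
#'   names.
#' @param L named numeric overrides for callable totals (e.g. NG86 site
#'   counts for synonymous/nonsynonymous).
#' @return a [site_class_map()].
#' @export
read_site_classes <- function(bed_paths, L = NULL) {
  ivs <- lapply(bed_paths, function(p) {
    df <- as.data.frame(fread(p, header = FALSE))
    bed_to_granges(df, what = basename(p))
  })
  names(ivs) <- names(bed_paths)
  site_class_map(ivs, L)
}

#' Write one class's intervals as BED (0-based half-open)
#' @param map a [site_class_map()].
#' @param site_class class to write.
#' @param path output path.
#' @export
write_bed <- function(map, site_class, path) {
  gr <- map$intervals[[site_class]]
  if (is.null(gr)) stop("class absent from map: ", site_class)
  fwrite(granges_to_bed(gr), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---- VCF ----

# per-sample GT strings -> c(alt_count, called_alleles) matrices
gt_counts <- function(gt) {
  called <- nchar(gsub("[^01]", "", gt))
  altn <- nchar(gsub("[^1]", "", gt))
  list(j = altn, n = called)
}

#' Read biallelic autosomal SNVs from a VCF
#'
#' Keeps biallelic single-nucleotide records on autosomes and computes, per
#' population, the alt-allele count `j` and called-chromosome count `n` from
#' the genotypes (missing genotypes reduce `n` for that site rather than
#' dropping it). An effect annotation INFO field (default `EFF`), when
#' declared in the header, is carried along for synonymous/nonsynonymous
#' labelling by [assign_site_class()].
#'
#' @param path VCF file.
#' @param populations named list: population id -> character vector of sample
#'   ids (must exist in the VCF header).
#' @param autosome_exclude regular expression for non-autosomal chromosome
#'   names to drop (default X/Y/MT under common naming schemes).
#' @param effect_field INFO field with the coding-effect tag (default
#'   `"EFF"`); silently absent fields give NA effects.
#' @return data.table sorted by (chrom, pos): chrom, pos, ref, alt, effect,
#'   class ("unassigned"), gene_id (NA), and j_<pop>, n_<pop> per population.
#' @export
read_vcf <- function(path, populations,
                     autosome_exclude = "^(chr)?(X|Y|MT?|W|Z)$",
                     effect_field = "EFF") {
  stopifnot(is.list(populations), length(populations) >= 1,
            !is.null(names(populations)))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  smp <- colnames(vcf)
  for (p in names(populations)) {
    missing_ids <- setdiff(populations[[p]], smp)
    if (length(missing_ids))
      stop("unknown sample id(s) in population '", p, "': ",
           paste(missing_ids, collapse = ", "))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(rr$REF)
  nalt <- S4Vectors::elementNROWS(rr$ALT)
  alt1 <- rep(NA_character_, length(rr))
  one <- nalt == 1
  alt1[one] <- as.character(unlist(rr$ALT[one]))
  keep <- nalt == 1 & nchar(refs) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    refs %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T") &
    refs != alt1 &
    !grepl(autosome_exclude, as.character(GenomicRanges::seqnames(rr)))
  eff <- rep(NA_character_, length(rr))
  inf <- VariantAnnotation::info(vcf)
  if (effect_field %in% colnames(inf)) {
    e <- inf[[effect_field]]
    if (is(e, "CharacterList")) e <- vapply(e, function(x)
      if (length(x)) x[[1]] else NA_character_, character(1))
    eff <- as.character(e)
  }
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                    pos = GenomicRanges::start(rr)[keep],
                    ref = refs[keep], alt = alt1[keep],
                    effect = eff[keep],
                    class = "unassigned", gene_id = NA_character_)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotypes")
  gt <- gt[keep, , drop = FALSE]
  for (p in names(populations)) {
    sub <- gt[, populations[[p]], drop = FALSE]
    j <- integer(nrow(out)); n <- integer(nrow(out))
    for (k in seq_len(ncol(sub))) {
      gc <- gt_counts(sub[, k])
      j <- j + gc$j; n <- n + gc$n
    }
    out[[paste0("j_", p)]] <- j
    out[[paste0("n_", p)]] <- n
  }
  setorder(out, chrom, pos)
  out[]
}

#' Write a variant table as VCF
#'
#' Genotypes are reconstructed from the per-population (j, n) counts: j alt
#' alleles are packed deterministically into homozygous-alt then heterozygous
#' genotypes, with `(2 * n_diploids - n) / 2` samples set missing. The
#' per-population counts therefore round-trip exactly through
#' [read_vcf()]; individual genotype configurations are bookkeeping, not
#' data.
#'
#' @param variants variant table.
#' @param path output path.
#' @param n_diploids named integer vector: samples per population (default:
#'   inferred as `max(n)/2` per population).
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, path, n_diploids = NULL) {
  pops <- populations_of(variants)
  if (is.null(n_diploids)) {
    n_diploids <- vapply(pops, function(p)
      as.integer(ceiling(max(variants[[paste0("n_", p)]]) / 2)), integer(1))
    names(n_diploids) <- pops
  }
  samples <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(n_diploids[[p]]))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hetexcess synthetic data",
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Coding effect tag">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  nr <- nrow(variants)
  gt_cols <- list()
  for (p in pops) {
    j <- variants[[paste0("j_", p)]]
    n <- variants[[paste0("n_", p)]]
    nd <- n_diploids[[p]]
    if (any(n %% 2 != 0) || any(n > 2 * nd))
      stop("cannot pack genotypes: need even n <= 2 * n_diploids for population ", p)
    hom <- j %/% 2L
    het <- j %% 2L
    called <- n %/% 2L
    cols <- lapply(seq_len(nd), function(k)
      ifelse(k <= hom, "1/1",
      ifelse(k <= hom + het, "0/1",
      ifelse(k <= called, "0/0", "./."))))
    gt_cols[[p]] <- do.call(paste, c(cols, sep = "\t"))
  }
  eff <- if ("effect" %in% names(variants)) variants$effect else rep(NA, nr)
  info <- ifelse(is.na(eff), ".", paste0("EFF=", eff))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", info, "GT",
                do.call(paste, c(gt_cols, sep = "\t")), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

## ---- class assignment ----

DEFAULT_EFFECT_MAP <- list(
  nonsynonymous = "missense|nonsynonymous|stop_gained|stop_lost|start_lost|non_synonymous",
  synonymous = "^synonymous|silent|^syn$"
)

#' Assign each variant to a site class (and gene)
#'
#' Coding variants are labelled synonymous/nonsynonymous from the effect
#' annotation tag when present (the pipeline never re-derives codon effects
#' from intervals); otherwise the class comes from interval overlap with the
#' map (a variant inside exome intervals without an effect tag stays class
#' "exome"). Variants matching nothing are "unassigned". A map whose intron
#' and intergenic intervals both cover a variant is inconsistent and raises
#' an error. Assignment is deterministic and independent of record order.
#'
#' @param variants variant table ([read_vcf()] output).
#' @param map a [site_class_map()].
#' @param genes optional gene feature table (gene_id, chrom, start0, end0,
#'   feature in \{"cds","intron"\}) used to attach `gene_id`.
#' @param effect_map named list of regexes mapping effect tags to
#'   nonsynonymous/synonymous.
#' @return the variant table with `class` (and `gene_id`) filled in.
#' @export
assign_site_class <- function(variants, map, genes = NULL,
                              effect_map = DEFAULT_EFFECT_MAP) {
  stopifnot(inherits(map, "site_class_map"))
  v <- as.data.table(variants)
  vgr <- GRanges(v$chrom, IRanges(v$pos, v$pos))
  hits <- function(cl) {
    gr <- map$intervals[[cl]]
    if (is.null(gr)) return(rep(FALSE, nrow(v)))
    GenomicRanges::countOverlaps(vgr, gr) > 0
  }
  in_intron <- hits("intron")
  in_intergenic <- hits("intergenic")
  both <- which(in_intron & in_intergenic)
  if (length(both))
    stop("site class map inconsistency: variant at ", v$chrom[both[1]], ":",
         v$pos[both[1]], " overlaps both intron and intergenic intervals")
  cls <- rep("unassigned", nrow(v))
  cls[hits("exome")] <- "exome"
  cls[in_intron] <- "intron"
  cls[in_intergenic] <- "intergenic"
  cls[hits("intergenic_distal")] <- "intergenic_distal"  # subset of intergenic
  if ("effect" %in% names(v)) {
    eff <- tolower(ifelse(is.na(v$effect), "", v$effect))
    cls[grepl(effect_map$synonymous, eff)] <- "synonymous"
    cls[grepl(effect_map$nonsynonymous, eff)] <- "nonsynonymous"
  }
  v$class <- cls
  if (!is.null(genes)) {
    ggr <- GRanges(genes$chrom, IRanges(genes$start0 + 1, genes$end0))
    ov <- GenomicRanges::findOverlaps(vgr, ggr, select = "first")
    v$gene_id <- ifelse(is.na(ov), NA_character_, genes$gene_id[ov])
  }
  v[]
}

#' Restrict the intergenic class to sites far from genes
#'
#' Adds an `intergenic_distal` class: intergenic intervals at least
#' `distance` bp from any gene span. Used as a neutral reference immune to
#' background selection from linked constrained sites.
#'
#' @param map a [site_class_map()].
#' @param genes gene feature table (gene_id, chrom, start0, end0, feature).
#' @param distance minimum distance from any gene (default 1e6 bp).
#' @return the map with class `intergenic_distal` added.
#' @export
distal_intergenic <- function(map, genes, distance = 1e6) {
  stopifnot(inherits(map, "site_class_map"))
  ig <- map$intervals[["intergenic"]]
  if (is.null(ig)) stop("map has no intergenic class")
  spans <- GRanges(genes$chrom, IRanges(genes$start0 + 1, genes$end0))
  wide <- GenomicRanges::reduce(spans + distance)
  distal <- GenomicRanges::setdiff(ig, wide)
  map$intervals[["intergenic_distal"]] <- distal
  map$L[["intergenic_distal"]] <- sum(as.numeric(GenomicRanges::width(distal)))
  map
}

## ---- score tracks and expression ----

#' Read a per-position conservation score track (bedGraph-like)
#'
#' Four tab-separated columns: chrom, start, end (0-based half-open), score.
#' Each covered position carries the interval's score.
#'
#' @param path bedGraph-like file.
#' @return data.table (chrom, start0, end0, score) of class `score_track`.
#' @export
read_scores <- function(path) {
  df <- suppressWarnings(fread(path, header = FALSE))
  if (nrow(df) == 0) {
    out <- data.table(chrom = character(), start0 = integer(),
                      end0 = integer(), score = numeric())
    class(out) <- c("score_track", class(out))
    return(out)
  }
  if (ncol(df) < 4) stop("score track needs 4 columns (chrom, start, end, score)")
  names(df)[1:4] <- c("chrom", "start0", "end0", "score")
  if (!is.numeric(df$score))
    stop("non-numeric score at line ", which(is.na(suppressWarnings(as.numeric(df$score))))[1])
  bad <- which(df$end0 <= df$start0)
  if (length(bad)) stop("score interval with end <= start at line ", bad[1])
  out <- df[, c("chrom", "start0", "end0", "score")]
  class(out) <- c("score_track", class(out))
  out
}

#' Expand a score track to one row per position
#'
#' Intended for small tracks and tests; genome-scale queries go through
#' interval arithmetic in [gene_constraint_proportion()].
#'
#' @param scores a `score_track`.
#' @return data.table (chrom, pos0, score), one row per covered position.
#' @export
expand_scores <- function(scores) {
  w <- scores$end0 - scores$start0
  data.table(chrom = rep(scores$chrom, w),
             pos0 = unlist(Map(seq, scores$start0, scores$end0 - 1)),
             score = rep(scores$score, w))
}

#' Read a gene expression table
#'
#' Tab-separated gene id and numeric (log-scale) mean expression; a header
#' line is auto-detected. Duplicate gene ids: last one wins, with a warning.
#'
#' @param path TSV file.
#' @return named numeric vector, names are gene ids.
#' @export
read_expression <- function(path) {
  df <- as.data.frame(fread(path, header = "auto"))
  if (ncol(df) < 2) stop("expression table needs 2 columns (gene id, value)")
  ids <- as.character(df[[1]])
  val <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(val)) stop("non-numeric expression value at line ", which(is.na(val))[1])
  dup <- duplicated(ids, fromLast = TRUE)
  if (any(dup))
    warning(sum(dup), " duplicate gene id(s) in expression table; last value kept")
  val <- val[!dup]; ids <- ids[!dup]
  stats::setNames(val, ids)
}

#' Read a gene feature table
#'
#' Tab-separated with header: gene_id, chrom, start0, end0, feature
#' ("cds" or "intron"), 0-based half-open.
#'
#' @param path TSV file.
#' @return data.table of gene features.
#' @export
read_gene_table <- function(path) {
  df <- fread(path, header = TRUE)
  need <- c("gene_id", "chrom", "start0", "end0", "feature")
  if (!all(need %in% names(df)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  bad <- which(df$end0 <= df$start0)
  if (length(bad)) stop("gene feature with end <= start at line ", bad[1])
  df[]
}
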