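## End-to-end driver chaining the stages: (simulate |) read -> class
## assignment -> per-class diversity -> excess -> gene strata, with a run
## manifest for reproducibility.

#' Pipeline configuration
#'
#' Defaults match the analysis conventions throughout the package: 1-Mb
#' blocks, 1000 bootstrap replicates, 1000-gene strata, constraint threshold
#' 2.0, nonsynonymous vs intron for delta.
#'
#' @param vcf,beds,site_counts,genes,gene_sites,scores,expression input file
#'   paths (`beds` is a named list class -> BED path; `site_counts` a TSV
#'   with columns class, L). All ignored when `simulate` is given.
#' @param simulate optional [sim_config()]: generate the inputs instead of
#'   reading files.
#' @param populations named list population id -> sample ids (ignored when
#'   simulating; the generator uses "large"/"small").
#' @param large_pop,small_pop which population is which.
#' @param constrained_class,neutral_class the delta comparison (defaults
#'   nonsynonymous vs intron).
#' @param block_size,B,bin_size,threshold,min_called,seed tuning knobs:
#'   bootstrap block size (1e6), replicates (1000), genes per stratum
#'   (1000), constraint-score cut-off (2.0), minimum called chromosomes per
#'   site (4), RNG seed (1).
#' @param out_dir output directory for the report tables.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, beds = NULL, site_counts = NULL,
                       genes = NULL, gene_sites = NULL, scores = NULL,
                       expression = NULL, simulate = NULL,
                       populations = NULL,
                       large_pop = "large", small_pop = "small",
                       constrained_class = "nonsynonymous",
                       neutral_class = "intron",
                       block_size = 1e6, B = 1000, bin_size = 1000,
                       threshold = 2.0, min_called = 4, seed = 1,
                       out_dir = tempfile("hetexcess_run_")) {
  cfg <- as.list(environment())
  if (is.null(simulate) && (is.null(vcf) || is.null(beds)))
    stop("either a sim_config or vcf + beds inputs are required")
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages: load or simulate inputs; assign site classes; per-class diversity
#' with block-bootstrap SEs; excess fraction delta with bootstrap; gene
#' strata by constraint and (when expression is available) by expression,
#' each with a Spearman trend test. Writes `diversity.tsv`, `excess.tsv`,
#' `strata_constraint.tsv`, `strata_expression.tsv`, `spearman.tsv` and
#' `manifest.json` into `out_dir`; partial outputs are removed on failure.
#' Identical config and seed reproduce every table byte for byte.
#'
#' @param cfg a [run_config()].
#' @return list with the result tables (diversity, excess, strata_*,
#'   spearman, manifest) and `out_dir`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  withCallingHandlers({
    emit <- function(x, name) {
      p <- file.path(cfg$out_dir, name)
      fwrite(as.data.table(x), p, sep = "\t")
      written <<- c(written, p)
      p
    }
    inputs <- list()
    if (!is.null(cfg$simulate)) {
      ds <- stage("simulate", generate_dataset(cfg$simulate))
      variants <- ds$variants
      map <- ds$map
      genes <- ds$genes
      gene_sites <- ds$gene_sites
      scores <- ds$scores
      expr <- ds$expression
      message("simulate: ", nrow(variants), " SNVs generated (seed ",
              cfg$simulate$seed, ")")
    } else {
      variants <- stage("read_vcf", read_vcf(cfg$vcf, cfg$populations))
      message("read_vcf: ", nrow(variants), " biallelic autosomal SNVs")
      L <- NULL
      if (!is.null(cfg$site_counts)) {
        sc <- fread(cfg$site_counts)
        L <- stats::setNames(sc$L, sc$class)
        L <- L[setdiff(names(L), "exome")]
      }
      map <- stage("read_site_classes", read_site_classes(cfg$beds, L = L))
      genes <- if (!is.null(cfg$genes)) stage("read_genes", read_gene_table(cfg$genes)) else NULL
      gene_sites <- if (!is.null(cfg$gene_sites)) fread(cfg$gene_sites) else NULL
      variants <- stage("assign_site_class",
                        assign_site_class(variants, map, genes = genes))
      scores <- if (!is.null(cfg$scores)) stage("read_scores", read_scores(cfg$scores)) else NULL
      expr <- if (!is.null(cfg$expression)) stage("read_expression", read_expression(cfg$expression)) else NULL
      inputs <- Filter(Negate(is.null),
                       cfg[c("vcf", "site_counts", "genes", "gene_sites",
                             "scores", "expression")])
      inputs <- c(inputs, cfg$beds)
    }
    n0 <- nrow(variants)
    variants <- filter_min_called(variants, cfg$min_called)
    message("filter: ", n0 - nrow(variants), " site(s) dropped with < ",
            cfg$min_called, " called chromosomes; per-class counts: ",
            paste(names(table(variants$class)), table(variants$class),
                  sep = "=", collapse = ", "))

    bi <- stage("partition_blocks",
                partition_blocks(variants, map, cfg$block_size))
    div <- stage("diversity",
                 diversity_with_bootstrap(bi, map, B = cfg$B, seed = cfg$seed))
    emit(div, "diversity.tsv")
    message("diversity: ", nrow(div), " (population, class) estimates over ",
            nrow(bi$blocks), " blocks")

    exc <- stage("excess",
                 excess_with_bootstrap(bi, map, cfg$large_pop, cfg$small_pop,
                                       cfg$constrained_class,
                                       cfg$neutral_class,
                                       B = cfg$B, seed = cfg$seed))
    emit(as.data.frame(exc), "excess.tsv")
    message(sprintf("excess: delta = %.1f%% (SE %.1f%%)",
                    exc$delta_percent, 100 * exc$se_delta))

    sp_rows <- list()
    strata_out <- list()
    if (!is.null(genes) && !is.null(gene_sites) && !is.null(scores)) {
      cp <- stage("constraint", gene_constraint_proportion(
        genes, scores, threshold = cfg$threshold))
      strat <- equal_count_bins(cp$constraint_prop, cp$gene_id, cfg$bin_size)
      st <- stage("strata_constraint", strata_delta(
        variants, stats::setNames(strat, cp$gene_id),
        stats::setNames(cp$constraint_prop, cp$gene_id),
        gene_sites, cfg$large_pop, cfg$small_pop))
      emit(st, "strata_constraint.tsv")
      strata_out$constraint <- st
      okst <- is.finite(st$delta_percent)
      if (sum(okst) >= 4) {
        sp <- spearman_test(st$mean_value[okst], st$delta_percent[okst],
                            seed = cfg$seed)
        sp_rows$constraint <- data.frame(stratifier = "constraint",
                                         rho = sp$rho, p_value = sp$p_value,
                                         p_t = sp$p_t, n = sp$n)
      }
    }
    if (!is.null(genes) && !is.null(gene_sites) && !is.null(expr)) {
      ids <- intersect(unique(genes$gene_id), names(expr))
      strat <- equal_count_bins(expr[ids], ids, cfg$bin_size)
      st <- stage("strata_expression", strata_delta(
        variants, stats::setNames(strat, ids), expr[ids],
        gene_sites, cfg$large_pop, cfg$small_pop))
      emit(st, "strata_expression.tsv")
      strata_out$expression <- st
      okst <- is.finite(st$delta_percent)
      if (sum(okst) >= 4) {
        sp <- spearman_test(st$mean_value[okst], st$delta_percent[okst],
                            seed = cfg$seed)
        sp_rows$expression <- data.frame(stratifier = "expression",
                                         rho = sp$rho, p_value = sp$p_value,
                                         p_t = sp$p_t, n = sp$n)
      }
    }
    spear <- if (length(sp_rows)) do.call(rbind, sp_rows) else NULL
    if (!is.null(spear)) emit(spear, "spearman.tsv")

    manifest <- list(
      package_version = as.character(packageVersion("hetexcess")),
      r_version = as.character(getRversion()),
      seed = cfg$seed, B = cfg$B, block_size = cfg$block_size,
      bin_size = cfg$bin_size, threshold = cfg$threshold,
      min_called = cfg$min_called,
      large_pop = cfg$large_pop, small_pop = cfg$small_pop,
      constrained_class = cfg$constrained_class,
      neutral_class = cfg$neutral_class,
      simulated = !is.null(cfg$simulate),
      inputs = if (length(inputs))
        lapply(inputs, function(p) list(path = p,
                                        md5 = unname(tools::md5sum(p))))
      else NULL,
      n_variants = nrow(variants))
    mp <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, mp)
    invisible(list(diversity = div, excess = exc, strata = strata_out,
                   spearman = spear, manifest = manifest,
                   out_dir = cfg$out_dir))
  }, error = on_fail)
}
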