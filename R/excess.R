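## The core statistic: the excess fraction delta of constrained-site
## heterozygosity segregating in the small population.
##
## Within each population, omega = pi_C / pi_N compares constrained-site to
## neutral-site diversity. Under neutrality omega_L = omega_S; purifying
## selection that is less effective in the small population inflates omega_S,
## and the inflation is summarised as delta = 1 - omega_L/omega_S
## (delta% = 100 * delta).

#' Constrained/neutral diversity ratio omega
#'
#' @param pi_C constrained-class diversity (>= 0), e.g. nonsynonymous or
#'   exome pi.
#' @param pi_N neutral-class diversity (> 0), e.g. intron, synonymous or
#'   distal-intergenic pi.
#' @return omega = pi_C / pi_N.
#' @export
omega_ratio <- function(pi_C, pi_N) {
  if (any(pi_N <= 0)) stop("neutral diversity is zero")
  if (any(pi_C < 0)) stop("pi_C must be >= 0")
  pi_C / pi_N
}

#' Excess fraction delta from the two omega ratios
#'
#' \deqn{\delta = 1 - \omega_L/\omega_S, \qquad
#'       \delta\% = 100\,(\omega_S - \omega_L)/\omega_S.}
#' delta is reported signed: a negative value (omega_L > omega_S) is flagged
#' `"negative_delta"`, not clipped, since the expected inequality
#' omega_L < omega_S is empirical, not a constraint.
#'
#' @param omega_L,omega_S within-population constrained/neutral diversity
#'   ratios of the large and small population (omega_S > 0).
#' @return list of class `excess_estimate`: omega_L, omega_S, delta,
#'   delta_percent, flags.
#' @examples
#' delta_excess(0.15, 0.22)  # the large population's omega is lower: delta ~ 0.32
#' @export
delta_excess <- function(omega_L, omega_S) {
  if (omega_S <= 0) stop("omega_S must be > 0")
  if (omega_L < 0) stop("omega_L must be >= 0")
  d <- 1 - omega_L / omega_S
  structure(list(omega_L = omega_L, omega_S = omega_S,
                 delta = d, delta_percent = 100 * d,
                 se_delta = NA_real_,
                 flags = if (d < 0) "negative_delta" else character(0)),
            class = "excess_estimate")
}

#' Excess fraction from cross-population diversity ratios
#'
#' Equivalent parameterisation using the large/small ratios of each class:
#' with \eqn{R_C = \pi_{CL}/\pi_{CS}} and \eqn{R_N = \pi_{NL}/\pi_{NS}},
#' \eqn{\omega_L/\omega_S = R_C/R_N}, so \eqn{\delta = 1 - R_C/R_N}. Agrees
#' with [delta_excess()] to machine precision when both are computed from the
#' same four diversities.
#'
#' @param R_C large/small ratio of constrained-class diversity (> 0).
#' @param R_N large/small ratio of neutral-class diversity (> 0).
#' @return delta (dimensionless).
#' @examples
#' 100 * delta_from_class_ratios(1.56, 2.26)  # 31.0
#' @export
delta_from_class_ratios <- function(R_C, R_N) {
  if (any(R_N <= 0)) stop("R_N must be > 0")
  if (any(R_C <= 0)) stop("R_C must be > 0")
  1 - R_C / R_N
}

#' @export
print.excess_estimate <- function(x, ...) {
  cat(sprintf("excess estimate: omega_L = %.4g, omega_S = %.4g\n",
              x$omega_L, x$omega_S))
  cat(sprintf("  delta = %.4f (%.1f%%)%s\n", x$delta, x$delta_percent,
              if (is.finite(x$se_delta)) sprintf(", SE = %.4f", x$se_delta) else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Excess fraction with joint block-bootstrap standard error
#'
#' The point estimate uses the four full-data diversities
#' (pi constrained/neutral in each population). Each bootstrap replicate
#' draws one shared block resample for all four quantities — preserving the
#' covariance between classes and populations that share genomic blocks —
#' and recomputes delta from pooled numerator and denominator sums.
#'
#' @param bi a [partition_blocks()] result (both populations' counts in the
#'   variant table).
#' @param map a [site_class_map()] supplying L_c denominators.
#' @param large_pop,small_pop population ids.
#' @param constrained_class,neutral_class class names (defaults:
#'   nonsynonymous vs intron, the primary comparison; synonymous and
#'   intergenic are selectable neutral alternatives).
#' @param B,seed bootstrap replicates (default 1000) and seed (default 1).
#' @return `excess_estimate` with `se_delta`, plus `pi` (the four
#'   diversities), `replicates`, `B`, `seed`.
#' @export
excess_with_bootstrap <- function(bi, map, large_pop, small_pop,
                                  constrained_class = "nonsynonymous",
                                  neutral_class = "intron",
                                  B = 1000, seed = 1) {
  stopifnot(inherits(bi, "block_index"))
  pops <- c(large_pop, small_pop)
  cls <- c(constrained_class, neutral_class)
  bs <- block_sums(bi, pops, cls)
  L_C <- class_L(map, constrained_class)
  L_N <- class_L(map, neutral_class)
  scl <- c(L_C / sum(bs$len[, constrained_class]),
           L_N / sum(bs$len[, neutral_class]))
  pi4 <- function(idx) {
    lc <- sum(bs$len[idx, constrained_class]) * scl[1]
    ln <- sum(bs$len[idx, neutral_class]) * scl[2]
    if (lc <= 0 || ln <= 0) return(rep(NA_real_, 4))
    c(CL = sum(bs$num[idx, constrained_class, large_pop]) / lc,
      NL = sum(bs$num[idx, neutral_class, large_pop]) / ln,
      CS = sum(bs$num[idx, constrained_class, small_pop]) / lc,
      NS = sum(bs$num[idx, neutral_class, small_pop]) / ln)
  }
  all_idx <- seq_len(nrow(bi$blocks))
  p <- pi4(all_idx)
  est <- delta_excess(unname(omega_ratio(p["CL"], p["NL"])),
                      unname(omega_ratio(p["CS"], p["NS"])))
  stat <- function(idx) {
    q <- pi4(idx)
    if (any(!is.finite(q)) || q["NL"] <= 0 || q["NS"] <= 0 || q["CS"] <= 0)
      return(NA_real_)
    1 - (q["CL"] / q["NL"]) / (q["CS"] / q["NS"])
  }
  bb <- block_bootstrap(bi, stat, B = B, seed = seed)
  est$se_delta <- bb$se
  est$pi <- p
  est$large_pop <- large_pop
  est$small_pop <- small_pop
  est$constrained_class <- constrained_class
  est$neutral_class <- neutral_class
  est$replicates <- bb$replicates
  est$B <- B
  est$seed <- seed
  est
}

#' Flatten an excess estimate to a one-row data.frame
#' @param x an `excess_estimate`.
#' @return one-row data.frame.
#' @export
as.data.frame.excess_estimate <- function(x, ...) {
  data.frame(
    large_pop = x$large_pop %||% NA_character_,
    small_pop = x$small_pop %||% NA_character_,
    constrained_class = x$constrained_class %||% NA_character_,
    neutral_class = x$neutral_class %||% NA_character_,
    omega_L = x$omega_L, omega_S = x$omega_S,
    delta = x$delta, delta_percent = x$delta_percent,
    se_delta = x$se_delta,
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
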