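## Nei-Gojobori (1986) synonymous/nonsynonymous site counting.
##
## Per codon position, the synonymous site fraction is the number of the 3
## possible single-nucleotide changes that preserve the amino acid, divided
## by 3; changes to stop codons count as nonsynonymous (classical
## convention). S + N equals the codon length exactly.

BASES <- c("A", "C", "G", "T")

# per-codon synonymous site count for all 64 codons, computed once
ng86_codon_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    syn <- vapply(codons, function(cod) {
      aa <- gc[[cod]]
      if (aa == "*") return(NA_real_)  # stop codons invalid inside a CDS
      s <- 0
      nt <- strsplit(cod, "")[[1]]
      for (posn in 1:3) for (b in setdiff(BASES, nt[posn])) {
        mut <- nt
        mut[posn] <- b
        maa <- gc[[paste(mut, collapse = "")]]
        if (maa != "*" && maa == aa) s <- s + 1
      }
      s / 3
    }, numeric(1))
    tab <<- syn
    tab
  }
})

#' Nei-Gojobori synonymous/nonsynonymous site counts for a CDS
#'
#' @param cds a single in-frame coding sequence (character string or
#'   `DNAString`), length divisible by 3, standard genetic code, no internal
#'   stop codons. A terminal stop codon, if present, is rejected like any
#'   other stop: strip it before counting.
#' @return named numeric vector `c(S = ..., N = ...)` with
#'   `S + N == nchar(cds)` exactly (to <= 1e-9).
#' @examples
#' ng86_site_counts("TTT")  # S = 1/3, N = 8/3: only TTT->TTC is synonymous
#' @export
ng86_site_counts <- function(cds) {
  cds <- toupper(as.character(cds))
  if (length(cds) != 1L) stop("cds must be a single sequence")
  len <- nchar(cds)
  if (len == 0 || len %% 3 != 0)
    stop("CDS length must be a positive multiple of 3, got ", len)
  codons <- substring(cds, seq(1, len, 3), seq(3, len, 3))
  bad <- grep("[^ACGT]", codons)
  if (length(bad))
    stop("non-ACGT character in codon ", bad[1], " ('", codons[bad[1]], "')")
  syn <- ng86_codon_table()[codons]
  stop_at <- which(is.na(syn))
  if (length(stop_at))
    stop("internal stop codon at codon ", stop_at[1], " ('", codons[stop_at[1]], "')")
  S <- sum(syn)
  c(S = S, N = len - S)
}

# draw a random stop-free CDS of n_codons codons (used by the generator)
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
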