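Package: hetexcess
Title: Excess Constrained-Site Heterozygosity in Small Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the excess fraction (delta) of constrained-site
    nucleotide diversity segregating in small populations relative to large
    ones. Implements per-site-class heterozygosity (Tajima's mean pairwise
    differences per site), the constrained/neutral diversity ratios omega and
    the excess statistic delta = 1 - omega_L/omega_S with 1-Mb block-bootstrap
    standard errors, gene stratification by selective constraint (PhyloP-style
    conservation) or expression with Spearman trend tests, Nei-Gojobori (1986)
    synonymous/nonsynonymous site counting, and a two-population synthetic-data
    generator with closed-form diffusion (Poisson random field) oracles for the
    expected diversity reduction under purifying selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    VariantAnnotation,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
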