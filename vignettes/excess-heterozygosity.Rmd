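---
title: "Quantifying excess constrained-site heterozygosity in small populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying excess constrained-site heterozygosity in small populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetexcess)
```

## The model and its assumptions

Nucleotide diversity at neutral sites is set by the product of effective
population size and mutation rate, π ≈ 4·N_e·μ, so a large population is
proportionally more diverse than a small one of the same species. At
constrained sites purifying selection removes variants, but its efficacy
scales with N_e·s: in a small population drift overwhelms weak selection and
mildly deleterious variants segregate that a large population would have
purged. The constrained-to-neutral diversity ratio ω = π_C/π_N therefore
rises as N_e falls, and the comparison of the two populations' ω values
isolates the effect:

δ = 1 − ω_L/ω_S

is the fraction of the small population's constrained-site heterozygosity
attributable to excess segregating (mostly deleterious) variation. The
derivation assumes (i) both populations share the same constrained and
neutral site annotations, (ii) the contribution of positive selection to
polymorphism is negligible, and (iii) neutral diversity differences between
the populations reflect N_e only (mutation rates do not differ). δ is a
ratio of ratios, so any site-ascertainment bias common to both populations
cancels; δ may legitimately be negative (ω_L > ω_S), and the package flags
rather than clips it.

π is estimated as Tajima's mean pairwise differences per site: at a
biallelic site with j alternate alleles among n called chromosomes the
unbiased per-site heterozygosity is 2j(n−j)/(n(n−1)), summed over SNVs of a
class and divided by the class's callable-site total L_c. The denominators
matter as much as the numerators: for synonymous/nonsynonymous classes L_c
is the Nei–Gojobori (1986) site count computed from CDS (per codon position,
the fraction of the three possible changes that are synonymous; mutations to
stops count as nonsynonymous; S + N equals the CDS length exactly). Callers
must supply L_c explicitly when coverage filters have reduced the callable
genome — interval lengths are only the default.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| block size | 1 Mb | bp | bootstrap resampling unit; large enough that linked sites travel together |
| bootstrap replicates B | 1000 | — | SE of δ stable to ~2% relative at this B |
| constraint threshold | 2.0 | conservation-score units (PhyloP-style) | conventional cut-off for calling a site constrained; strictly greater-than |
| genes per category | 1000 | genes | equal-count stratification used for the constraint and expression trends |
| min. called chromosomes | 4 | chromosomes | sites with n < 4 in either population are dropped: the per-site estimator's variance explodes at tiny n |
| neutral class | intron | — | synonymous sites are weakly constrained; distal intergenic (≥ 1 Mb from genes) available where background selection is a worry |

The bootstrap draws one shared block resample per replicate for all four π
values entering δ and recomputes δ from pooled numerator and denominator
sums (a ratio of sums, not a mean of ratios). Sharing the resample preserves
the covariance between classes and populations that occupy the same blocks;
resampling each π independently would overstate SE(δ).

## What the generator emulates — and what it does not

`generate_dataset()` draws segregating sites from the stationary
Wright–Fisher diffusion spectrum f(q; γ) ∝
(1−e^{−γ(1−q)})/((1−e^{−γ}) q(1−q)) with γ = 4·N_e·s (semidominant fitness
1, 1−s, 1−2s), site counts Poisson with mean θ_site·L·∫f, frequencies by
inverse-CDF lookup on a 10^4-point grid uniform in logit(q) between
1/(2N_e) and 1−1/(2N_e) (the logit grid resolves the 1/q spike that a
uniform grid of the same size misses). Sample allele counts are
j ~ Binomial(2·n_diploids, q) — the exact Hardy–Weinberg sampling
distribution — and the VCF writer packs j into individual genotypes
deterministically, so individual-level genotype configurations carry no
information beyond (j, n). Neutral classes (intron, intergenic, synonymous)
use γ = 0; nonsynonymous sites of gene g use the gene's γ_g. Synthetic
conservation scores are a·log(1+|γ_g|) plus Gaussian noise per CDS position,
and expression is b·log(1+|γ_g|) plus noise, encoding the empirical
constraint–expression correlation.

Two closed-form oracles accompany the generator. The expected
selected/neutral diversity ratio integrates to

r(γ) = 2·(1 − (1−e^{−γ})/γ) / (1−e^{−γ}),

validated in the tests against adaptive quadrature to below 1e-8 relative
error (r(0) = 1, r(−10) ≈ 0.200), and the implied excess for two population
sizes sharing s is δ = 1 − r(−4·N_eL·s)/r(−4·N_eS·s), N_e-weighted per gene
when s varies. A slow forward Wright–Fisher simulation at tiny N_e
(infinite-sites, semidominant selection, binomial drift) cross-checks the
diffusion spectrum in the test suite.

Deliberate non-features, which green tests therefore do not establish
anything about: the two populations are simulated independently at
equilibrium — no shared ancestry, migration, linkage or background
selection, and no non-equilibrium demography. δ compares per-population
equilibrium diversities, so divergence structure is irrelevant to its
definition, but real data carry linkage disequilibrium that the block
bootstrap is designed to absorb and the generator only mimics by placing
sites in contiguous blocks. Dominance variation and distributions of fitness
effects beyond per-gene constants are likewise out of scope.

Defaults describe a desk-scale caricature of the chimpanzee contrast:
N_e 60,000 vs 10,000, μ = 1.25e-8 (θ_L = 0.003), γ_L = −10, 10 diploids per
population, 200 genes (999 bp CDS, 2.5 kb intron) and one distal intergenic
window per 7-Mb chromosome, totalling ≈ 1e6 neutral and ≈ 1.5e5
nonsynonymous callable sites in 56 one-Mb blocks. Where the source analyses
used genome-scale data (e.g. 1000 genes per category), tests scale the world
down and say so in place.

## Numerical and design choices

- Coordinates: VCF positions are 1-based; BED/bedGraph files are 0-based
  half-open. Internally intervals live in GenomicRanges (1-based closed) —
  the Bioconductor convention — with conversion confined to the file
  boundary.
- Equal-count binning sorts by stratifier with ties broken by gene id;
  consecutive chunks of `bin_size`; a remainder shorter than half a bin
  merges into the last chunk, otherwise it stands alone (14,870 genes at
  1000/bin give 15 categories, 9,089 give 9, matching the published
  category counts).
- Coding variants are classified synonymous/nonsynonymous from a VCF
  annotation tag (an SnpEff-style effect field); the package never
  re-derives codon effects from intervals. NG86 counting supplies only the
  denominators.
- Bootstrap replicates on which δ is undefined (a resample with zero
  neutral or zero constrained diversity) are excluded from the SE with a
  logged count; more than 10% undefined aborts, since the SE would no
  longer be trustworthy.
- Missing genotypes reduce n at a site rather than dropping the site;
  sites with n < 4 in either population are excluded from π.
- `exome` is defined as the union of synonymous and nonsynonymous CDS
  sites (UTRs excluded), so its L_c is the NG86 S + N total, which equals
  the CDS length exactly.
- The per-category neutral reference for gene strata is the stratum's own
  intron π by default (`neutral = "stratum"`); a genome-wide intron
  reference is available (`"global"`) since the source analyses do not pin
  this down.
- Spearman trend tests report a permutation p (add-one corrected, so
  p ≥ 1/(n_perm+1)) alongside the t-approximation; rank correlation is
  used because neither the linearity nor the error distribution of the
  δ%-vs-stratifier relationship is known.
- The position-collision rule in the generator (infinite sites): duplicated
  positions are redrawn within their gene/window up to 30 rounds, then the
  rare stragglers are dropped with a message, preserving site counts to a
  few parts in 1e4.

## Known limitations

Real VCFs bring complications the pipeline accepts but does not model:
variable per-site coverage interacts with the explicit-L_c requirement (the
caller must supply callable totals consistent with their coverage filters);
admixed individuals should be removed upstream; and δ's interpretation as
"excess deleterious variation" leans on the neutrality of the reference
class — introns under selection would bias δ downward. The bootstrap treats
1-Mb blocks as exchangeable, which understates uncertainty if diversity is
strongly autocorrelated beyond 1 Mb. Finally, δ quantifies the excess
relative to the large population; it is not an absolute measure of load,
and comparisons of δ across species pairs inherit each pair's N_e contrast.
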