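---
title: "Aggregated trans-effect scores: model, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated trans-effect scores: model, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcores)
```

## The model

For a target gene $g$, let $\beta_{gj}$ be the marginal effect of SNP $j$
on its expression, estimated in a large external GWAS of expression (or of
circulating protein levels). The pipeline turns these summary statistics
into per-individual genotypic scores in four steps.

**Clumping.** Records are retained at $p < 10^{-5}$ and grouped, per
chromosome, by single-linkage chaining: consecutive retained SNPs less
than 1 Mb apart join the same clump, so emitted clumps are pairwise
separated by at least 1 Mb. A clump must contain a lead SNP with
$p < 10^{-6}$. The retention threshold is deliberately laxer than a
genome-wide significance level: the aim is prediction, not per-locus
discovery. Chaining was chosen over greedy lead-SNP windows because it is
deterministic and order-free; the separation property ("clumps at least
1 Mb apart") holds either way, but chaining does not depend on which SNP
is examined first.

**LD adjustment.** For the member SNPs of a clump, genotype correlations
$R$ are estimated in a reference panel and the marginal effects are mapped
to joint weights
$$ w = (R + \lambda I)^{-1} \beta, $$
which approximate the coefficients of a multiple regression of expression
on all clump SNPs jointly. The default ridge $\lambda = 10^{-3}$ exists
purely for numerical safety — clumped reference-panel correlation matrices
are routinely near-singular — and is configurable down to 0, recovering
plain inversion. Before inversion, near-duplicate variants
($|r| > 0.99$) are pruned, keeping the member with the smaller p-value.
The tests verify the approximation directly: on simulated clumps of 2–10
SNPs with within-clump correlation up to 0.9, the adjusted weights agree
with individual-level joint least-squares coefficients within three
joint-fit standard errors.

**Locus scores and classes.** An individual's locus score is the dot
product of their dosages with $w$. A clump is *cis* if its distance to the
target's transcription site is at most 50 kb (inclusive — a locus at
exactly 50 kb is cis), *cis-x* between 50 kb and 5 Mb, *trans* beyond 5 Mb
or on another chromosome. Distance is the minimum gap between any member
SNP and the nearer site boundary, zero when the intervals overlap; it is
symmetric upstream/downstream. Cis-x loci are reported as their own class
and never enter trans aggregation.

**Aggregation, diversity, association.** The genome-wide trans-score is
the plain (unweighted) sum of the target's trans locus scores, excluding
every clump that overlaps the HLA region (chromosome 6, 25–34 Mb; any
overlap excludes), scaled to unit standard deviation in the full analysis
sample. Summing before standardizing matches the definition of the score
as a sum; the variances $\sigma_i^2$ entering the diversity index are
those of the unstandardized locus scores in the same sample. The effective
number of contributing eQTLs is the Hill number
$$ N_\mathrm{eff} = 2^{-\sum_i p_i \log_2 p_i}, \qquad
   p_i = \sigma_i^2 \Big/ \sum_k \sigma_k^2 , $$
which equals $K$ for $K$ equally contributing loci and 1 when a single
locus dominates. Each unit-SD score is tested by maximum-likelihood
logistic regression with the first three genotypic principal components as
covariates (the per-SNP GWAS additionally adjusts for sex and age; both
covariate sets are configurable). The standardized log odds ratio $b$
yields the information for discrimination $b^2/2$ in natural-log units.

**Selection.** A target is called a putative core gene when
$N_\mathrm{eff} > 5$ and $p < 10^{-9}$ (diversity criterion) or when it is
a known monogenic disease gene and $p < 10^{-6}$. Both inequalities are
strict, read literally from "greater than 5" / "more than two"; no
multiple-testing correction is applied because selection uses fixed
thresholds. A gene meeting both criteria is recorded once, under
diversity. Clumps contributing to scores associated below $10^{-9}$ are
pooled and union-merged into regions; a region feeding strictly more than
two such scores is flagged as a putative peripheral master regulator.

## What the synthetic generator emulates

The generator exists so that every operation above is exercisable, with
known ground truth, at desk scale.

*Genotypes.* Haplotypes are exchangeable-binary within blocks: each
allele equals a block-shared Bernoulli($p$) draw with probability
$\sqrt{\rho}$, else an independent draw, giving exact pairwise allele (and
dosage) correlation $\rho$ inside a block, independence across blocks,
Hardy–Weinberg dosages, and one allele frequency per block drawn from the
configured range. This is the simplest mechanism with controllable LD; it
produces no long-range decay, no haplotype blocks of varying extent, and
no population structure.

*Genome layout.* Blocks of 5 SNPs (1 kb spacing) sit 12 Mb apart on
synthetic chromosomes, so distinct blocks are always in mutual trans;
the designated HLA blocks sit inside chr6 25–34 Mb. Gene transcription
sites are placed at block boundaries with offsets chosen so cis, cis-x and
trans clump–gene pairs all occur.

*Architecture.* Each gene has one cis effect at its home block. Each core
gene receives trans effects from 12 unlinked blocks: 10 exclusive plus 2
master-regulator blocks shared by all core genes. Bystander genes draw
their 12 trans blocks from the same core pool — that is precisely what
makes them confounded bystanders — and two designated bystanders are
"HLA-driven": strong trans effects from the HLA blocks, only three weak
ones elsewhere. Genes hit different (mutually correlated) SNPs within a
shared block. Effect magnitudes are drawn as
$\mathrm{scale} \times e^{N(0,\,0.25)}$ with random sign; a pure Gaussian
draw would put most trans effects below the summary-statistic retention
threshold, making the number of detectable loci per gene — and hence the
attainable diversity — uncontrollable. Per gene, trans effects are
rescaled so the trans share of genetic expression variance equals the
configured fraction (default 0.7, the share typically attributed to
trans-acting variation in blood).

*Disease.* Liability is logistic:
$\mathrm{logit}\,P(\text{case}) = \alpha + \sum_g \gamma_g z_g + \delta
\sum_b u_b$, where $z_g$ are the core genes' standardized genetic
expression values, $u_b$ standardized HLA causal dosages ($\delta = 0.5$
per block), and $\alpha$ sets a base rate of 0.1. Cases and controls are
ascertained exactly to quota by batch sampling. The default
$|\gamma| = 0.6$ comes from a power calculation at the default study size
(1,000 cases / 1,000 controls): the Wald SE of a unit-SD score in a
balanced study of $n$ individuals is about $2/\sqrt{n} \approx 0.045$, so
the realized score log OR of roughly $0.6 \times \sqrt{0.7} \times 0.86
\approx 0.4$ (trans share captured, times the attenuation from the other
liability components) gives $z \approx 9$, comfortably beyond the
$z \approx 6.1$ that $p < 10^{-9}$ requires, while bystander scores —
whose correlation with liability is diluted by roughly $1/\sqrt{12}$ —
stay well below it.

*Summary statistics.* A disjoint expression-GWAS cohort (default
n = 20,000) yields single-SNP regression records per gene. Mirroring large
trans-eQTL meta-analyses, which test only a restricted trait-associated
SNP panel in trans, trans records are emitted only for SNPs in
liability-linked blocks topped up to a configured fraction (default 0.6)
of the genome; all SNPs within 5 Mb of a gene's site are reported for that
gene.

*Genotypic PCs.* Principal-component loadings are learned among controls
and all individuals are projected onto them. In a compact synthetic genome
with no population structure, PCs computed on the case-enriched combined
sample align with the liability direction (ascertainment inflates variance
along it) and would absorb genuine signal; control-learned loadings mirror
the real situation, where PCs reflect ancestry rather than disease.

## What passing tests do and do not show

The recovery suite shows that, under this architecture, diversity-criterion
selection attains sensitivity ≥ 0.8 for true core genes with a false-call
rate ≤ 0.05 among bystanders, and that HLA exclusion silences genes driven
only by the confounded HLA region. It does not show that the method is
robust to realistic LD decay, imputation error, allele-frequency spectra,
cryptic relatedness, or population stratification — none of which the
generator produces. Type-I calibration (rejection rate 0.05 ± 0.02 at
α = 0.05 over 1,000 null replicates of n = 2,000) is a property of the
logistic fit under a correctly specified null, not of model robustness.

## Numerical choices and degenerate inputs

- Intervals are 1-based and closed throughout; all boundary comparisons
  (50 kb cis bound, 200 kb known-hit window, HLA overlap) are inclusive.
- Summary statistics are harmonized to the genotype panel: swapped
  effect/other alleles flip the sign of β, unmatched allele pairs are
  dropped, and strand-ambiguous A/T and C/G variants with panel MAF > 0.4
  are dropped.
- Missing dosages are mean-imputed per variant before correlations and
  scores.
- A clump with no panel-matchable variants, a singular post-pruning LD
  system, or a zero-variance aggregate is skipped with a warning and
  recorded, never silently imputed.
- Non-converged or separated logistic fits are flagged and excluded from
  selection; a duplicated-score covariate is reported as non-converged
  rather than yielding a silent estimate.
- The Hill number uses the convention $0 \log 0 = 0$ and rejects all-zero
  variance vectors.

## Problem sizes

The default study conditions are a 20,000-individual expression GWAS, a
1,000-reference-individual LD panel, and a 1,000/1,000 case-control study
over 46 LD blocks (230 SNPs) and 12 genes. The recovery suite runs 20
seeded replicates of the full pipeline at these sizes; the null-calibration
suite runs 1,000 replicates at 2,000 individuals with a minimal
architecture. These sizes were chosen so that the power calculation above
holds while a full test run remains a desk-scale computation.

## Known limitations

- The eight HLA risk-score variables are a synthetic stand-in for
  published class I / class II tagging schemes: five tag dosages, a
  class-II double-heterozygote indicator, a class-II dosage product, and a
  class-I carrier composite. The exact published derivation lives in an
  external reference and is not reproduced here.
- The case-only interaction test assumes score independence in the
  population; the generator satisfies this by construction, real data may
  not.
- Whether the original analysis standardized locus scores before or only
  after summation is not documented anywhere; this package sums raw locus
  scores and then standardizes, matching the definition of the score as a
  sum.
- The two-sample assumption (expression GWAS disjoint from the
  case-control study) is a modelling choice; overlap between cohorts would
  induce correlated errors the pipeline does not model.
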