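---
title: "Effective chromosome segments and the accuracy of genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective chromosome segments and the accuracy of genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gprelate)
```

## The model

Genomic prediction estimates the effects of genome-wide markers in a
*discovery* sample of N phenotyped individuals and projects them onto
*target* individuals to produce genetic profile scores. How accurate those
scores can be is governed by three quantities: the heritability h², the
discovery size N, and the **effective number of independent chromosome
segments** Mₑ whose effects must, in effect, be estimated. The expected
correlation between true and estimated scores is

r = √( b · N h² b / (N h² b + Mₑ) ),

with b = M/(M + Mₑ) the fraction of genetic variance captured by M observed
variants (b ≈ 1 for dense panels). The correlation with phenotypes is √h²
times r.

Mₑ is where the population design enters. For a population with effective
size Nₑ, the expected squared LD correlation between two loci at distance c
Morgan is r²(c) = 1/(1 + 4Nₑc), or 1/(2 + 4Nₑc) when recurrent mutation is
accounted for. Packing M equally spaced SNPs onto a chromosome gives an
M × M squared-correlation matrix **S**; the number of effectively
independent SNPs is the sum of the weights solving **S**w = 1
(`meFromWeights()`), well approximated by M²/ΣS (`meMatrixMean()`). Letting
M → ∞, one chromosome of L Morgan yields the closed form

1/Mₑ = 2∫₀¹ (1 − x) r²(xL) dx
     = 2[(a + β)ln((a + β)/β) − a]/a²,  a = 4NₑL,

with β = 1 (drift only) or β = 2 (mutation-corrected)
(`meClosedFormSingle()`). Chromosomes are not independent: a random pair of
individuals shares recent pedigree ancestors, which correlates their
relationships across chromosomes. Summing the variance contributed by
common ancestry over past generations gives a between-chromosome covariance
of 1/(3Nₑ), so for n chromosomes the genome-wide value averages an n × n
matrix with diagonal 1/Mₑ,single and off-diagonal 1/(3Nₑ)
(`meClosedFormGenome()`). For 30 chromosomes of 1 Morgan this produces
Mₑ ≈ 254 at Nₑ = 100 and ≈ 21,248 at Nₑ = 10,000:

```{r}
sapply(c(100, 500, 2000, 5000, 10000), function(ne)
  round(meValue(meClosedFormGenome(populationGenome(ne, nChr = 30)))))
```

The same quantity can be measured from data: for a GRM A built from
standardized dosages, the variance of the relationships between target
individual i and discovery individuals j estimates 1/Mₑ
(`meFromGRM()`). This is the empirical bridge: designs that place close
relatives of target individuals into the discovery set inflate the variance
of A_ij and so *reduce* the effective Mₑ, which raises accuracy exactly as
if Nₑ were smaller.

## Disease traits

For case-control designs the liability threshold model applies: disease
status indicates an underlying standard-normal liability exceeding the
threshold t with P(liability > t) = K. With a discovery sample of
case-fraction P, the liability-scale h² maps to the ascertained 0/1 scale
as h²₀₁ = h² z² P(1 − P) / (K²(1 − K)²), and the expected score accuracy is
the quantitative formula evaluated at h²₀₁ (`accuracyCaseControl()`). From
the score-liability correlation r = √h² · ρ follow

* the expected AUC, Φ( r(i − i₂) / √(2 − r²[i(i − t) + i₂(i₂ − t)]) ),
  where i = z/K and i₂ = −z/(1 − K) are the mean case and control
  liabilities (`expectedAUC()`);
* the expected odds ratios contrasting score percentiles: within a stratum
  of the score distribution with truncated-normal mean i_s and threshold
  t_s, liability is normal with mean r·i_s and variance
  1 − r² i_s(i_s − t_s), so the stratum disease risk is a probit expression
  and odds ratios follow (`expectedOR()`), against either the bottom
  stratum or the whole population (reference odds K/(1 − K)).

These stratum formulas treat the within-stratum score as truncated normal;
a bivariate-normal Monte Carlo check (in the test suite) shows the AUC
expression is accurate to three decimals, while the bottom-stratum risk is
slightly overstated at high accuracy, making the top-vs-bottom odds ratio
conservative (the expected 131.9 at Nₑ = 100 compares with ≈ 155 by direct
simulation of the same bivariate-normal model). We keep the analytic form:
it is the quantity the downstream comparisons are defined against.

```{r}
runTheoryCurves(c(100, 1000, 10000))
```

## Predictors

`gblupPredict()` implements GBLUP, ĝ_target = G_td (G_dd + λI)⁻¹ y with
λ = (1 − h²)/h²; `snpBlupPredict()` is the algebraically identical ridge
regression on jointly standardized SNPs (the identity is asserted to 1e-8
in the tests). h² is supplied by the user, never estimated; for
case-control data the 0/1 status is the response directly, since any
two-valued recoding of the response only rescales the scores. A diagonal
jitter of 1e-8 stabilizes the factorization; systems are solved directly.

## The simulators and what they do (not) emulate

**Gene dropping** (`simulateGenedrop()`): a monoecious Wright-Fisher
population of Nₑ breeders, each offspring drawing two parents at random
with replacement (selfing allowed), gametes recombining with
Poisson(chromosome length) crossovers at uniform positions (Haldane, no
interference) and per-site symmetric mutation. Founder haplotypes start
with independent sites at frequency 0.5 — with a mutation rate of 1e-8 and
a few hundred generations, mutation alone cannot create the required
polymorphism, so drift from a polymorphic founder state is what shapes the
spectrum and LD. Discovery and target samples larger than Nₑ are drawn by
generating that many offspring from the final breeding population
("expansion sampling"); they constitute one extra generation of the same
population. Phenotypes attach normal effects to a random causal subset of
MAF-passing sites, rescaled so the causal SNPs explain exactly h² of the
phenotypic variance in-sample. Defaults mirror the full single-chromosome
validation design (Nₑ = 500 for 500 generations, 20,000 sites, samples of
2000/1000, h² = 0.01); the test suite exercises a desk-scale configuration
chosen once — Nₑ = 100, 200 generations, 2000 sites, 1 Morgan, samples of
500/250, 500 causal sites, h² = 0.10, 20 replicates — large enough for the
drift-LD equilibrium to establish while keeping a replicate to a few
seconds. Because the simulator's mutational input is negligible, its
validation compares against the drift-only (β = 1) closed form. What this
simulator does not emulate: recombination hotspots, mutation-drift
equilibrium at realistic human time depths, selection, or non-uniform
marker spacing — passing validation here supports the drift/recombination
core of the theory, not those features.

**Liability case-control** (`simulateCaseControl()`): mₛ unlinked SNPs with
frequencies U(0.05, 0.95) (results are frequency-insensitive after
standardization; the range merely avoids near-monomorphic draws), normal
effects scaled to liability-variance h², residual N(0, 1 − h²), affected
above the K-threshold. Discovery cases are collected by rejection sampling
(capped at 50·N/K draws); the target is an unascertained sample, mirroring
population screening. With unlinked SNPs, mₛ *is* Mₑ by construction, so
theory and simulation can be compared without a population model. The
validation conditions are the reference design: mₛ = 254, h² = 0.5,
K = 0.1, P = 0.5, N = 3000, target 30,000, with 10 replicates.

**Sib families** (`simulateSibFamilies()`): unlinked-SNP full-sib families
used to exercise the design contrast — splitting within families places
sibs across the discovery/target boundary, inflating relationship variance
(small Mₑ, high accuracy), while family-wise splits keep them apart. Only
the direction of the contrast is meaningful here; real-cohort magnitudes
depend on pedigree depth and LD that these fixtures do not model.

## Numerical choices

* Normal quantiles/densities come from R's `qnorm`/`dnorm`/`pnorm`
  (relative error well below 1e-10); no series approximations.
* The SNP-spacing convention places M SNPs with spacing L/(M − 1),
  endpoints included; the M → ∞ limit is insensitive to this choice.
* `meFromWeights()` adds a ridge of 1e-8 and warns when the correlation
  matrix's condition number exceeds 1e12 (perfect-LD blocks are singular).
* `meFromGRM()` uses the population (1/n) variance of the pooled
  discovery × target block — at hundreds of thousands of block entries the
  1/(n − 1) alternative is indistinguishable; the per-target variance
  vector is exposed for diagnostics and ranking.
* GRM standardization uses allele frequencies computed jointly over
  discovery and target, the field-standard VanRaden form; missing dosages
  are mean-imputed per SNP and monomorphic SNPs dropped with a warning.
* Dichotomization and percentile strata break ties by stable sort order;
  stratum boundaries sit at floor(n·q). Observed odds ratios use the
  contingency cross-product with the Haldane-Anscombe 0.5 correction on
  zero cells, flagged.
* Reported Mₑ stays a float; integer comparisons round half away from
  zero. Zero map length returns Mₑ = 1 rather than dividing by zero.
* Validation replicates use seeds `seed + replicate`, making every run
  bit-reproducible.

## Known limitations

The genome closed form assumes equal chromosome lengths (the numeric
single-chromosome path takes any length). The ascertained-scale h²
transformation is a first-order approximation that overstates the
realizable 0/1-scale signal somewhat for common diseases with h² around
0.5 — in the validation runs the observed AUC sits about 0.008 below the
expectation (well within the replicate interval), and joint ridge
estimation can conversely exceed the marginal-score accuracy law when
N ≫ Mₑ. Expected odds ratios inherit the truncated-normal stratum
approximation noted above. None of the expected quantities come with
confidence intervals; the validation workflows quantify spread empirically
instead.
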