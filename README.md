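# gprelate

Theory and tools linking **relatedness between discovery and target
samples** to the accuracy of genomic prediction, for quantitative traits
and disease (case-control) designs.

The accuracy of a genetic profile score estimated from N phenotyped
individuals is

r = √( N h² / (N h² + Mₑ) ),

where Mₑ is the effective number of independent chromosome segments. Mₑ is
a function of the effective population size Nₑ and the genome layout: for a
chromosome of L Morgan, 1/Mₑ = 2[(a+β)ln((a+β)/β) − a]/a² with a = 4NₑL
(β = 2 with the mutation-corrected LD formula r² = 1/(2 + 4Nₑc)), and
chromosomes combine through a between-chromosome relationship covariance of
1/(3Nₑ). Equivalently, Mₑ is the reciprocal of the variance of genomic
relationships between target and discovery individuals — so study designs
that include relatives of the target in the discovery set *lower* Mₑ and
raise accuracy, which is the central design message this package
quantifies. For disease traits the chain continues through the liability
threshold model to expected AUC and percentile odds ratios.

The package provides:

* closed-form, numeric-matrix and GRM-based Mₑ estimators
  (`meClosedFormGenome()`, `meFromWeights()`, `meMatrixMean()`,
  `meFromGRM()`);
* expected accuracy, AUC and odds-ratio calculators
  (`accuracyQuantitative()`, `accuracyPhenotypic()`,
  `accuracyCaseControl()`, `expectedAUC()`, `expectedOR()`);
* GBLUP / SNP-BLUP profile-score prediction (`gblupPredict()`,
  `snpBlupPredict()`) with GCTA-format GRM I/O (`readGRM()`, `writeGRM()`);
* two validation simulators — forward-in-time gene dropping
  (`simulateGenedrop()`) and independent-SNP liability-threshold
  case-control data (`simulateCaseControl()`) — plus observed-performance
  metrics (`observedAUC()`, `observedOR()`, `decileORProfile()`) and
  bundled workflows (`runTheoryCurves()`, `runValidation()`).

A thin command-line front end lives at `inst/scripts/gprelate.R`
(subcommands `liability`, `me`, `me-grm`, `expect`, `theory-curves`,
`gblup`, `simulate-genedrop`, `simulate-cc`, `metrics`, `validate`).

## Worked example

A typical GWAS-scale design — N = 3000 discovery individuals, h² = 0.5, a
30-chromosome genome of 1 Morgan each, disease prevalence K = 0.1 with a
50/50 case-control discovery set:

```r
library(gprelate)
runTheoryCurves(c(100, 1000, 10000))
#>      Ne         Me     rTrue    rPheno       auc orTopBottom  orTopPop
#> 1   100   253.5588 0.9248802 0.6539890 0.8482138  131.992368 23.009812
#> 2  1000  2313.1606 0.6271957 0.4434943 0.7379461   14.874817  7.319590
#> 3 10000 21248.4408 0.2567851 0.1815745 0.5974218    2.682013  2.333764
```

Reading the first row: with close relatedness between discovery and target
(Nₑ = 100) the genome behaves as ≈ 254 independent segments, the profile
score correlates 0.65 with phenotype, discriminates cases at AUC 0.85, and
the top 1% of scores carries 23-fold higher disease odds than the
population. With distant relatedness (Nₑ = 10,000) the same data yield
r = 0.18 and AUC 0.60.

The empirical side of the bridge, on simulated gene-dropped genotypes:

```r
cfg <- genedropConfig(Ne = 100, generations = 200, nSites = 2000,
                      nDiscovery = 500, nTarget = 250, nCausal = 500,
                      h2 = 0.1)
runValidation("genedrop", cfg, replicates = 20, seed = 100)
#>   quantity observedMean observedSD  expected    lower     upper covered
#> 1       Me     40.80438  2.6675625 39.928557 35.57595 46.032799    TRUE
#> 2 accuracy      0.72144  0.0526567  0.745652  0.61823  0.824648    TRUE
```

The variance of discovery-target relationships recovers the theoretical
Mₑ within a few percent, and the observed GBLUP accuracy brackets the
expectation.

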