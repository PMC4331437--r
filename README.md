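# retroMosaic

Somatic retroelement insertion analysis from suppression-PCR junction
libraries.

## The scientific problem

L1 (LINE-1) and Alu retroelements still copy themselves in human genomes.
When a new copy integrates in a somatic cell it creates genetic mosaicism:
an insertion carried by one cell lineage of one tissue and absent everywhere
else. Junction-library sequencing makes such events detectable: genomic DNA
is digested with blunt restriction enzymes (AluI + HaeIII for L1,
AluI + RsaI for Alu), suppression adapters are ligated, and nested
subfamily-specific primers (targeting L1Hs and AluYa5, the young, active
subfamilies) amplify the fragment spanning one element/genome junction —
the L1 3' junction or the Alu 5' flank. Read 1 starts inside the element
terminus and crosses into unique genomic flank, pinning the insertion to a
single base.

With per-tissue libraries from one individual, a call is classified by
cross-library comparison:

* **reference** — matches an element annotated in the reference assembly;
* **germline / polymorphic** — non-reference, present in *all* libraries;
* **potentially somatic** — non-reference, present in *exactly one*
  library;
* **ambiguous** — non-reference, present in some but not all libraries
  (kept out of both somatic and germline tallies).

Because discovery scales with depth, each library is summarised by its
normalized rate, `100 × somatic-representing reads / total reads`. The
statistical battery on top:

* **Exact conditional Poisson rate test** for two libraries (or one vs the
  pooled rest): condition on `T = x1 + x2`; under equal rates
  `x1 ~ Binomial(T, n1/(n1+n2))`; two-sided minimum-likelihood p-value.
* **Monte-Carlo genomic-distribution test**: 1000 uniform coordinate sets
  of the observed size; empirical enrichment/depletion p-values
  `(1 + #extreme)/(R + 1)` for genic and promoter (5 kb upstream of the
  TSS) compartments.
* **Overdispersion test** for homogeneity of grouped proportions:
  `D = Σ (xᵢ − nᵢ·p̄)² / (nᵢ·p̄·(1−p̄))` against χ² on k−1 df.
* **Exact binomial orientation test** of co- vs counter-orientation of
  genic/promoter insertions against 0.5.

The package implements the full computational pipeline (a sequence-level
simulator of the library chemistry, a toy seed-and-extend junction mapper,
cross-library classification, strand-aware gene/promoter annotation, and
the statistics), and ships the published five-tissue count tables
(cerebellum, frontal cortex, SVZ, dentate gyrus, myocardium) as a fixture
whose every derivable number it recomputes.

## A worked example

Simulate a five-tissue L1 experiment on a 3 Mb toy genome (the dentate
gyrus somatic rate is 1.5× the other tissues by default), run the pipeline,
and test the focal tissue against the pooled rest:

```r
library(retroMosaic)
cfg <- simulationConfig(families = "L1Hs")
res <- runPipeline(cfg, seed = 11, mcReplicates = 200)
res$summary
#>           tissue total_reads somatic_reads somatic_insertions rate_pct
#> 1     cerebellum        1057           149                125    14.10
#> 2 frontal_cortex        1121           148                120    13.20
#> 3            SVZ        1116           154                121    13.80
#> 4  dentate_gyrus        1177           235                180    19.97
#> 5     myocardium        1135           151                118    13.30
```

The dentate gyrus shows the planted ~1.5× excess in its normalized rate
(19.97% vs ≈13–14%; toy-genome rates are much larger than real-library
rates because the simulated libraries carry no background). Calls match the
planted truth almost perfectly, and the rate excess is highly significant:

```r
somaticAccuracy(res)
#>      family  tp called truth precision recall
#> L1Hs   L1Hs 664    664   682         1  0.974

res$stats$L1Hs$focalVsPooled
#> 	Exact conditional two-sample Poisson rate test (minlike)
#> data:  235/1177 vs 602/4429
#> p-value = 1.219e-06
```

Recompute every derivable number of the published count tables (rates,
compartment percentages, grand totals, detection fractions, and the test
battery) with

```r
audit <- auditCountTable()
subset(audit, !pass)   # only the documented non-reproducible printed claims
```

`poissonRateTest(1376, 11978540, 1353, 10921385)` reproduces the printed
cerebellum-vs-SVZ Alu p-value 0.0506, and `orientationTest(691, 1465)` the
printed dentate-gyrus genic Alu p-value 0.032.

A thin command-line wrapper with `simulate`, `run`, `call`, `import` and
`audit` subcommands is installed at
`system.file("scripts", "retromosaic.R", package = "retroMosaic")`.

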