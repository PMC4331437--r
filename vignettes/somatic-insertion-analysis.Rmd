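---
title: "Detecting somatic L1 and Alu insertions from junction libraries"
author: "retroMosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic L1 and Alu insertions from junction libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroMosaic)
```

## The problem

Retroelements — LINE-1 (L1) and the non-autonomous Alu elements it
mobilises — continue to copy themselves in human genomes. Most new
insertions arise in the germ line, but insertions in somatic cells create
genetic mosaicism within one individual, and neural tissue, in particular
the dentate gyrus (the niche of adult neurogenesis), is a suspected hotspot.
The experimental design this package models compares the concentration of
*somatic* L1Hs and AluYa5 insertions across five tissues of a single donor:
cerebellum, frontal cortex, subventricular zone (SVZ), dentate gyrus and
myocardium.

The measurement instrument is a suppression-PCR junction library: genomic
DNA is cut with blunt restriction enzymes (AluI + HaeIII for L1, AluI + RsaI
for Alu), suppression adapters are ligated, and nested subfamily-specific
primers selectively amplify the fragment containing one junction between an
element terminus and its unique genomic flank — the 3' junction for L1
(LINEs are usually 5'-truncated), the 5' flank for Alu (avoiding the 3'
polyA tail). Sequencing read 1 therefore begins inside the element terminus
and crosses the junction into the flank, which pins the insertion to a
single base.

An insertion is called **potentially somatic** when (i) its coordinate does
not match any annotated reference-genome element of the same family, and
(ii) it is seen in exactly one tissue library. Insertions seen in every
library are polymorphic or novel **germline** insertions; matches to the
assembly are **reference** copies. We add an explicit
`ambiguous_multi_tissue` class for calls seen in 2..k−1 libraries, so the
two extreme classes are never silently inflated by in-between cases.

## What the package provides

* a sequence-level simulator of the whole experiment
  (`simulateLibraries()`): synthetic genome with genes and embedded
  reference-RE termini, planted germline/somatic events, restriction-digest
  fragment logic, and paired FASTQ + truth BED output;
* the computational half of the protocol (`screenReads()`, `mapFlanks()`,
  `collapseCalls()`, `classifyInsertions()`, `summarizeLibraries()`);
* strand-aware gene/promoter annotation (`buildAnnotationIndex()`,
  `locateInsertions()`), the promoter being the 5,000 bp immediately
  upstream of the TSS on the gene's strand;
* the statistical battery (`poissonRateTest()`, `rateVsPooledTest()`,
  `monteCarloDistributionTest()`, `overdispersionTest()`,
  `orientationTest()`);
* the packaged published count tables and their full recomputation
  (`countsFixture()`, `auditCountTable()`).

## The statistics

**Normalized rate.** The number of detected somatic insertions scales with
library depth, so each library is summarised by the percentage of reads that
represent potentially somatic insertions,
$100 \cdot r_\mathrm{som} / r_\mathrm{tot}$.

**Exact conditional Poisson rate test.** To compare two libraries' somatic
read rates $x_1/n_1$ and $x_2/n_2$, condition on $T = x_1 + x_2$; under the
equal-rate null $x_1 \sim \mathrm{Binomial}(T,\, n_1/(n_1+n_2))$. The
two-sided p-value uses the minimum-likelihood convention (sum the
probabilities of all outcomes no more likely than the observed one) — the
dominant convention in statistical software, adopted here because the test
is named but its convention is not stated in print. The choice is validated
by reproducing the printed cerebellum-vs-SVZ Alu p-value of 0.0506 exactly.
One library against the pooled rest (`rateVsPooledTest()`) is the same test
on element-wise sums.

**Monte-Carlo genomic-distribution test.** To ask whether insertions favour
genes or promoters, draw $R = 1000$ coordinate sets of the observed size $N$
uniformly over the genome (chromosome proportional to length, offset
uniform), count genic and promoter hits per replicate, and report empirical
p-values with the add-one estimator $(1 + \#\{\mathrm{sim} \ge
\mathrm{obs}\})/(R+1)$, which cannot be zero. The simulated mean ± SD
reproduces the error-bar presentation of the original figures. No
mappability mask is applied — none is stated in print — but real-data use
can pass a masked gene set.

**Overdispersion test.** Homogeneity of compartment fractions across
tissues is tested with
$D = \sum_i (x_i - n_i\bar p)^2 / (n_i \bar p (1-\bar p))$,
$\bar p = \sum x / \sum n$, against $\chi^2_{k-1}$ (upper tail). The
original analysis cites a quality-control package without spelling out the
statistic; this construction is the standard grouped-proportion
overdispersion chi-square. On the printed counts it yields large p-values
(0.94 for genic L1 fractions, 0.9978 for the orientation fractions) but not
the printed "p > 0.98 in all cases" / "p = 0.9999"; `auditCountTable()`
reports these rows as computed, with an honest fail flag, rather than tuning
the statistic to match.

**Orientation test.** Within genic (or promoter) insertions, co-orientation
(element strand equal to gene strand) is tested against 0.5 with the exact
binomial minimum-likelihood two-sided p-value; the printed dentate-gyrus
genic Alu value of 0.032 (691 co of 1465) is reproduced exactly.

## The simulator: what the defaults mean

The generator's defaults define the synthetic study conditions; they were
fixed once, by design, and the validation suite runs against them.

| parameter | default | rationale |
|---|---|---|
| genome | 3 × 1 Mb | large enough for unique 25–67 bp flanks, small enough for a laptop-scale run |
| gene fraction | 0.40 | order of the genic fraction of the human assembly |
| gene length | 10–60 kb uniform | keeps ~35 genes per Mb with 5 kb promoters ≈ 6% promoter space |
| somatic rate | 50 events/Mb/family; dentate gyrus L1 75 (1.5×), dentate gyrus Alu 100, frontal cortex Alu 80 | mirrors the relative rates of the study; the absolute rate is scaled up so a 3 Mb genome yields enough somatic reads for the rate tests to have power (a priori power analysis: ~650 conditional trials give >90% power at α = 0.01 for a 1.5× excess) |
| germline events | 30/family | scaled from the hundreds of non-reference germline insertions seen genome-wide |
| reference copies | 60 L1, 150 Alu | keeps the ~1:2.6 L1:Alu annotation ratio and dominates library depth, as in real libraries |
| read length | 101 bp | the sequencing configuration modelled |
| germline/reference reads | Poisson(12) per library | many-read support for events present in all cells |
| somatic multiplicity | {1: 0.85, 2: 0.08, 3: 0.04, 4: 0.02, 5: 0.01} | somatic insertions are seen "overwhelmingly by one read", never more than 4–5 |
| error rate | 0.1%/base | Illumina-scale substitution noise; indels are not modelled |
| co-orientation probability | L1 0.41, Alu 0.48 | the observed genic co-oriented fractions |
| genic multiplier | L1 1.25, Alu 1.0 | L1 insertions are enriched in genes; Alu matches the uniform expectation |
| min flank | 25 bp | below this a junction fragment is uninformative |
| suppression cap | 3 kb | fragments without a cut site within 3 kb of the junction fail suppression PCR; the real size window is unpublished, so this is exposed as configuration |

Insertion points are 0-based inter-base coordinates; target-site
duplications are not modelled because calling resolves a single junction
side only. Enzymes are palindromic blunt 4-cutters cut mid-site, and
recognition scanning runs on the insertion-bearing sequence, so an insertion
can create or destroy sites exactly as physical digestion would. Only the
junction-proximal terminus of an element is inserted; cut sites falling
"beyond" it stand in for cuts in the element body. The terminus consensus
sequences are synthetic stand-ins that embed the genuine subfamily-specific
primer sequences used for library construction; their tails are designed so
no recognition site can span the junction, which keeps primer loss a
property of the genome, not of the element model.

What the simulator deliberately does **not** emulate: PCR duplicates and
chimeras, indel errors, quality-score variation, polyA tails, mappability
structure, target-site duplications, and the repeat-rich context of real
flanks. Passing tests therefore demonstrate the correctness of the
computational pipeline and the calibration of the statistics under clean
junction chemistry — not robustness to every artifact of real libraries.

## Numerical and design choices

* **Coordinates.** 0-based half-open internally and in all BED output;
  human-readable reports are 1-based. An insertion at 0-based junction $j$
  is the point query at 1-based base $j+1$.
* **Mapping.** Exact 20 bp seed (PDict) plus full-flank extension with ≤2
  substitutions; a flank is kept only when exactly one extension passes —
  ambiguous flanks are discarded, never rescued, because calling requires
  single-base resolution. Reads whose flank runs into the suppression
  adapter are trimmed (internal exact match of the adapter's first 10 bp,
  then partial terminal overlap ≥ 3 bp), the standard read-through
  treatment.
* **Collapse.** Reads within 3 bp on the same chromosome and element strand
  chain-merge to the modal coordinate, ties toward the smaller coordinate;
  collapse is idempotent.
* **Reference matching.** A call within 100 bp of the junction-proximal end
  of a same-family annotated element on the same strand is a reference
  rediscovery.
* **Classification ceiling.** No read-count ceiling is applied to the
  somatic class by default — the low read support of somatic insertions is
  an observation, not a filter; `maxSomaticReads` exists for users who want
  one.
* **Empty inputs.** Zero reads give empty summaries with missing (NA) rates
  and an explicit "no reads" log line; a zero denominator never becomes a
  zero rate.
* **Recall denominator.** Somatic recall is measured against amplifiable
  truth events — those whose fragment survives digestion with the primer
  site intact and ≥ 25 bp flank. Events that produce no library molecule
  are invisible to any caller; the suppression-loss tally enumerates them.

## Problem sizes used by the test suite

Unit tests run on 2 × 120 kb genomes with 2–8 kb genes. The end-to-end
recovery checks use the default 3 Mb five-tissue configuration with the L1
family (20 replicates under the 1.5× dentate-gyrus excess and 20 under an
equal-rate null); Monte-Carlo calibration uses $N = 3000$ insertions and
$R = 1000$ replicates. These sizes were chosen so the whole suite runs on a
single CPU in well under half an hour while keeping every stochastic
tolerance at 3 standard errors or better.

## Known limitations

* The toy mapper is for synthetic genomes; real data should be mapped
  externally (the original analysis used Bowtie2) and imported with
  `importAlignments()`.
* The exact filtering cascade applied to the real libraries is unpublished;
  `screenReads()` implements declared, configurable stand-ins.
* The printed orientation table contains one internally inconsistent row
  (cerebellum genic Alu: 323 + 301 ≠ 623); the fixture keeps the printed
  values verbatim and the audit flags the row.
* The overdispersion construction reproduces the direction (large p, no
  excess variability) but not the printed p-values exactly; see above.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(families = "L1Hs")
res <- runPipeline(cfg, seed = 11, mcReplicates = 200)
res$summary                      # per-library rates; dentate gyrus highest
somaticAccuracy(res)             # precision/recall against the planted truth
res$stats$L1Hs$focalVsPooled     # dentate gyrus vs pooled rest

audit <- auditCountTable()       # recompute the published tables
subset(audit, !pass)
```
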