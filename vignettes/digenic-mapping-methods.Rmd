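---
title: "Methods: simulating and mapping a digenic recessive trait"
author: "digenicBSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping a digenic recessive trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenicBSR)
```

This vignette documents the models behind `digenicBSR`, the defaults and why
they were chosen, the numerical decisions, and what the package's synthetic
data can and cannot tell you about real experiments.

## The genetic model

The trait is **digenic recessive epistatic**: two unlinked nuclear loci
(PY1 on chromosome A09, PY2 on A07 in the default genome), each with a wild
allele and a recessive mutant allele; a plant expresses the mutant (yellow,
chlorophyll-deficient) phenotype if and only if it is homozygous mutant at
*both* loci. Neither locus alone produces the phenotype. Under this model

* the F1 of a mutant × wild cross is uniformly green (and identical in both
  reciprocal directions, which is the nuclear-inheritance diagnostic
  implemented in `inferInheritanceMode()`);
* the F2 segregates green : yellow = 15 : 1;
* the backcross to the mutant parent segregates 3 : 1;
* selfed green F2 plants found families in proportions
  all-green : (3:1-segregating) : (15:1-segregating) = 7 : 4 : 4; and
* among selfed green plants of a 3:1 family, segregating : non-segregating
  families = 2 : 1.

`expectedComposition()` derives all of these by exhaustive enumeration of
parental gamete combinations with exact integer weights — none of the ratios
is hard-coded, and the test suite cross-checks the enumeration against an
independent brute-force implementation. The package also accepts a
single-locus genome (the same machinery then yields 3:1 / 1:1 expectations),
which is useful as a monogenic control: the generalisation is deliberate
even though the primary design is digenic.

## Meiosis and the breeding simulator

`drawGametes()` implements a Poisson crossover process on the genetic (cM)
axis with no interference: the number of crossovers between consecutive loci
at distance $d$ Morgans is Poisson($d$), cumulated along the chromosome, and
the starting haplotype is chosen fairly. Two consequences matter:

* the recombination fraction between any two loci follows the **Haldane**
  transform $r = (1 - e^{-2d})/2$, which gives a closed-form oracle for
  Monte-Carlo tests (e.g. loci 50 cM apart recombine at
  $(1-e^{-1})/2 \approx 0.3161$);
* **Kosambi** distances, which the estimation side reports (as linkage
  analyses in this field conventionally do), are not the exact inverse of
  the generating process. The mismatch is second-order at the small $r$
  relevant to fine mapping (both functions satisfy
  $100r \le d \le d_{Haldane}$ and agree to first order), and the package
  treats it as a documented modelling asymmetry rather than trying to make
  the simulator Kosambi-consistent, which would require an interference
  model with no comparably simple oracle.

`simulateStudy()` propagates founders (fully homozygous doubled-haploid
lines, the mutant carrying the alternate allele at every marker, so all
markers are informative) through the study design: selfed parent lines (92
and 120 plants), reciprocal F1s (258, 226), an F2 of 2376, backcrosses to
both parents (669, 720), twenty F2:3 families from selfed green F2 plants,
and F3:4 families from eight selfed green plants of each 3:1-classified
F2:3 family. Those generation sizes are the study conditions; the F2:3 and
F3:4 family sizes (100, 150 by default) are simulation choices — the source
design does not fix them — set large enough that a 3:1 family is essentially
never confused with 15:1.

Two stochastic failure modes of the design itself are surfaced rather than
hidden. If no F2:3 family classifies as 3:1, `simulateStudy()` errors
("re-seed or enlarge"). If the realized 3:1 families all segregate the same
locus (probability ≈ 11% with twenty selfed F2 plants), the other locus has
no mapping family; `runPipeline()` handles both by deterministically
re-drawing the breeding simulation with a seed derived from the global seed
(attempt $i$ uses seed + 7919·(i−1)), mirroring the fact that the original
strategy was only carried through because the drawn families covered both
loci.

## Pooled sequencing and the ED⁵ scan

`simulateBulkCounts()` samples 100 green and 100 yellow F2 plants without
replacement, computes each pool's true mutant-allele frequency at every
locus, then draws per-SNP depth as Poisson(30) and mutant-allele reads as
Binomial with the error-adjusted frequency $f(1-e) + (1-f)e$ (symmetric
substitution error, default $e = 0.001$; one parameter, invertible). The
depth default is a package choice — pooled designs of this kind do not
dictate one — and the >3× per-pool depth screen is interpreted as *total
depth ≥ 4 in each pool*.

At a causal locus the yellow pool is fixed for the mutant allele
($f_Y = 1$), while green F2 plants carry wild/het/mutant genotypes 4:8:3 at
either causal locus, giving $f_G = 7/15$; both values come from the same F2
enumeration used for the segregation expectations, and the simulator is
tested against them. The ED statistic uses both allele-frequency
coordinates, $ED = \sqrt2\,|f_G - f_Y|$ (the √2 is immaterial for the
scale-free top-quantile rule), raised to the fifth power; the significance
threshold is the $\lceil 0.01 n \rceil$-th largest ED⁵ with ties included,
and regions are maximal runs of flagged loci with inter-locus gaps ≤ 2 Mb
and at least 2 members. Interval length is reported as end − start (the
convention that reproduces marker-to-marker span arithmetic exactly), with
1-based inclusive coordinates throughout.

**Marker density.** The default genome carries 600 markers per chromosome
(~50 kb spacing). This is the one generator default that was revised after
measurement: at 30× pooled depth, the top-1% tail of ED⁵ is dominated by
depth-noise outliers, and at ~100 markers/chromosome the handful of flagged
loci frequently failed to bracket the causal position, so called regions
missed it. Real pooled-transcriptome scans of this design detect on the
order of 15,000 SNPs per chromosome and produce Mb-scale regions containing
tens of flagged loci each; 600/chromosome is the desk-scale density at
which the simulated scan reproduces that geometry (regions of ~2–50 flagged
loci, median ≈ 25), and at which region recovery of both causal loci is
≈ 98% over seeded replicates. Densities below ~300/chromosome are not
recommended with the default depth.

## Fine mapping

Mapping populations are **recessive-class**: every individual is homozygous
mutant at the target locus, so each plant contributes two independently
scored gametes at a linked marker — genotype H is one recombinant gamete, B
is two, A is none, and $r = R/2N$ with missing cells reducing $2N$. The
pipeline grows a large F3:4 mapping family (default 6,000 plants ≈ 1,500
yellow, the scale such studies genotype) from the parent of the best
segregating family, simulating only the target chromosome: the parent is
homozygous mutant at the other locus, so phenotype segregates with the
target locus alone and nothing is lost by the restriction.

`delimitInterval()` anchors the target at the span of co-segregating
(R = 0) markers, or at the minimum-$r$ marker when none co-segregates, and
takes as flanks the minimum-$r$ marker with $R > 0$ on each physical side
of the anchor. A co-segregating marker can never bound the interval, and an
anchor marker that itself has recombinants is treated as inside — a
deliberately conservative rule, since without phase information its side
cannot be determined; full multipoint ordering is out of scope (dedicated
mapping software exists for that). Recombinants on one side only produce a
flagged one-sided interval. Genes are intersected with the interval under
the any-overlap rule (a gene straddling a boundary is included).

## Expression stage

RPKM is $10^9 \cdot \text{count} / (\text{libSize} \cdot \text{length})$;
genes with RPKM ≥ 0.1 in at least one pool count as expressed. Because the
two pools are single pooled libraries without replicates, no dispersion
model is identifiable; the DEG test is the conditional exact two-proportion
test of the two counts against the library-size split
(`binom.test(c_Y, c_Y + c_G, p = N_Y/(N_G+N_Y))`), with Benjamini–Hochberg
adjustment over all expressed genes and the DEG rule |log₂FC| ≥ 1 and
FDR ≤ 0.05. The fold change uses a pseudocount of 1 read per pool
(configurable) to handle zeros. The test function is pluggable for users
who prefer a different two-library statistic.

The library-size normalisation is total counts; when a large fraction of
high-expression genes is differentially expressed in one direction this
estimator absorbs part of the signal (the usual composition effect). The
default synthetic scenario — 90 genes up, 91 down (the two causal genes
among them, downregulated 4-fold) out of 2,000, at a pinned expected count
of 300 — keeps that bias small by balancing directions, and the DEG caller
recovers ≈ 181 DEGs with ≈ 90 upregulated plus a handful of
FDR-consistent false positives.

`ddctRelativeExpression()` implements the 2^−ΔΔCt method for qPCR
validation of a candidate against a reference gene and calibrator sample.

## Numerical and reporting conventions

* Segregation ratios are rounded **half-up** to two decimals (base R's
  banker's rounding would differ on exact halves); chi-square values are
  reported at two decimals the same way.
* The Yates correction truncates at zero: a perfect fit gives χ² = 0.
  The correction is the default because the conventional reported values
  for these designs follow it (the uncorrected statistics differ at the
  second decimal, e.g. 1.73 vs 1.62 on the F2 counts); it can be disabled.
* The critical value defaults to 3.84 (χ²₀.₀₅, df = 1) and is configurable.
* `all_green` classification requires literally zero yellow plants.
* Family classification assigns the hypothesis with the smaller chi-square
  when both 3:1 and 15:1 pass; families rejected by both are `other`. At
  family size 100 this leaks ~2% of segregating families into `other`,
  which slightly depresses the 3:1 class proportion relative to the exact
  7:4:4 — visible in large classification experiments and inherent to the
  fixed-critical-value rule, not a simulator bias.
* All stochastic stages take seeds derived from a single global seed; a
  pipeline run is byte-reproducible given the seed, and the config hash is
  recorded in the run provenance.

## Problem sizes used by the test suite

Tests run at the sizes a laptop handles in minutes, chosen as the package's
own desk-scale conditions: 100 seeded F2 simulations (n = 2376) for the
15:1 recovery, 2,000 F2:3 families for the 7:4:4 classification, 50 seeded
ED⁵ scans (pools of 100 at 30×, 600 markers/chromosome) for region
recovery, recombination-recovery at N = 1520 for r ∈ {0.001, 0.01, 0.05},
and a 2,000-gene expression scenario. Marker-free sparse genomes are used
where only segregation is under test, since the marker panel does not
influence phenotype ratios.

## What the synthetic data does and does not show

The generator emulates: Mendelian transmission with Haldane recombination,
pool composition sampling, binomial read sampling with a symmetric error
rate, Poisson expression counts with configured fold changes. It does not
emulate read-level artefacts (alignment error, mapping bias, duplicate
reads), segregation distortion or viability selection, interference in
meiosis, overdispersed expression counts, or a real gene annotation.
Passing tests therefore demonstrate that the *statistics and algorithms*
behave as specified under the stated stochastic model — not that the
pipeline is robust to the failure modes of real sequencing data. Real-data
totals (genome-wide SNP counts in the 10⁵ range, tens of thousands of
expressed genes, sub-Mb final intervals from thousands of genotyped plants)
are beyond desk scale and are not reproduced; the package reproduces the
statistical geometry of each stage instead.
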