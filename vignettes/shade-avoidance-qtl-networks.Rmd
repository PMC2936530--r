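---
title: "Mapping plasticity QTL and prioritizing candidate regulators with sarnet"
author: "sarnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping plasticity QTL and prioritizing candidate regulators with sarnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarnet)
```

## The problem

Plants sense neighbor shade through a reduced red:far-red light ratio and
respond with the shade avoidance syndrome: elongation, leaf movement and, in
annuals like *Arabidopsis thaliana*, accelerated flowering. The genetic
dissection of this *plasticity* — the change of a trait between environments
rather than the trait itself — proceeds in two steps that `sarnet`
implements as one tested pipeline:

1. **Plasticity QTL mapping.** Grow a recombinant inbred line (RIL)
   population under simulated sun and simulated shade, condense plant-level
   measurements into per-line condition indices, derive shade-avoidance
   response (SAR) indices, and run an interval-mapping genome scan with
   permutation-based significance thresholds and 2-LOD support intervals.
2. **Candidate-gene prioritization.** A support interval contains dozens to
   hundreds of genes. For each candidate the pipeline fuses four
   genome-wide evidence layers — co-expression (mutual ranks over a
   microarray compendium), expression QTL (eQTL) colocalization, shared
   GO-Slim biological-process terms, and protein/cis-regulatory
   polymorphism — into a directed network, and ranks candidates by their
   number of functionally coherent connections.

Because the real inputs of such a study (multi-environment RIL phenotypes,
an expression compendium, an eQTL atlas, genome annotation, resequencing
polymorphisms) are large and heterogeneous, the package ships a
synthetic-data generator that produces every input with planted ground
truth. All statistical guarantees quoted below are verified by the test
suite on generated data.

## Condition indices and the two SAR indices

Plant-level values are collapsed per line and treatment in two stages
(`computeConditionIndices`). First, each declared nuisance factor (chamber,
flat, measurer, ...) is screened with a one-way F-test on the residuals from
the current line-by-treatment means; when significant at `screenAlpha`
(default 0.05) its residual level means are subtracted. Factors are visited
once, in the given order. Second, the index is the mean of adjusted values
per line and treatment. This is the balanced-design analogue of declaring
the factors as random effects "when significant" in a mixed model, without
the REML machinery; for balanced designs the adjustment is unbiased. One
caveat is inherent: a factor shift is only identified up to a constant
shared by all plants, so condition indices after adjustment can differ from
the unperturbed ones by a single global constant. No downstream quantity
(SAR indices, LOD scores, effects) can see that constant, and the test suite
asserts invariance up to it.

Two SAR indices are computed per line (trait units):

* **subtraction index** = sun index − shade index; exact arithmetic, and
  exactly invariant to location shifts of the raw phenotypes.
* **residual index** = −(shade − b₀ − b₁·sun), the negated residual of an
  OLS regression of shade indices on sun indices. By construction it has
  mean zero and zero sample correlation with the sun index (asserted to
  1e-9). Higher values mean a stronger response in both indices.

**Normality gate.** Before scanning, each trait's line indices pass a
Shapiro–Wilk test; when rejected at p < 0.01 the indices are replaced by
their natural logarithm (no offset is ever silently added — non-positive
values are an error). The test statistic is computed on indices centered
within condition, so the sun/shade location difference is not mistaken for
non-normality. Whether the gate is better applied to plant-level data or
to line indices is a modeling choice; `sarnet` applies it to line indices
(gate plant-level data yourself before index computation if preferred).

**A documented limitation of the residual index.** The regression slope is
attenuated by measurement error in the sun index: b₁ ≈ V_shared/(V_shared +
V_meas). A *constitutive* QTL (equal effect a in both environments)
therefore leaks an effect (1 − b₁)·a into the residual index. With the
generator defaults (below) the leaked LOD is ≈ 0.3 and the residual scan
stays below threshold for constitutive QTL (asserted at ≥ 90% of
replicates), but with noisy indices (V_meas comparable to the index
variance) the leak can reach genome-wide significance. The subtraction
index does not suffer from this; under the default generator both indices
agree with rank correlation > 0.9, mirroring the usual empirical finding
that the two give similar scans.

## Interval mapping

`calcGenoprob` computes P(B | flanking markers) on a pseudomarker grid
(default step 1 cM). RIL genotypes along a chromosome form a Markov chain
with transition probability R = 2r/(1 + 2r) per interval, where r is the
Haldane single-meiosis recombination fraction r = (1 − e^(−2d/100))/2; this
is the standard map expansion for inbreeding by selfing taken at its F∞
limit (residual heterozygosity of finite-generation lines is ignored —
genotypes are strictly biallelic homozygous). Missing genotypes are bridged
by conditioning on the nearest non-missing flanks; a line with no typed
marker on a chromosome is an error.

`scanIM` is Haley–Knott regression: the index is regressed on the expected
genotype score E[g] = 2·p_B − 1 at each grid position, and

* LOD = (n/2)·log10(RSS₀/RSS₁), against the intercept-only model,
* a = half the fitted difference between B and S homozygotes
  (a > 0 ⇔ the B allele increases the index; swapping parent labels negates
  a exactly),
* PVE = 1 − RSS₁/RSS₀, so PVE = 1 − 10^(−2·LOD/n) holds identically.

For complete RIL data at typed markers this equals the full
maximum-likelihood interval mapping fit, and the suite asserts equality
with an independent `lm()` oracle to 1e-9. Everything is computed as
centered cross-products, so a genome scan and a thousand permutations are a
single matrix product.

**Thresholds.** `permutationThreshold` permutes index values across lines
and takes the empirical (1 − α) quantile (nearest-rank; α = 1 returns the
minimum permuted maximum) of the genome-wide maximum LOD. A common
choice at publication scale is 10,000 permutations; the pipeline default
is 1,000, which is calibrated to the same α (the Monte-Carlo error simply
shrinks with more permutations). Calibration — a null scan exceeds its own
5% threshold in 5% ± 2% of replicates — is asserted over 400 replicates at
1,000 permutations each.

**Support intervals.** `supportInterval` finds the genome-wide peak
(leftmost on ties) and returns the contiguous run of grid positions with
LOD ≥ LOD_peak − drop (default drop = 2), up to but not including the first
positions falling below the cutoff; a drop of 0 degenerates to the peak
point. Bounds are anchored to bp by linear interpolation between markers
and exported as 0-based half-open BED. A peak below the significance
threshold still yields an interval, flagged and with a warning. Coverage of
the planted locus by the 2-LOD interval is asserted at ≥ 90% over 200
replicates (n = 253, effect = residual SD).

**Informative subsets.** `selectInformativeSubset` re-estimates the effect
at a target position in many random line subsets (default size 126) and
returns the subset maximizing |a| (LOD optionally). The draw budget is
`nIter` (tens of thousands of draws are cheap since only the target
position is re-fit); the maximization target is the additive effect, with
LOD available as an alternative.

## The evidence network

For every gene overlapping the candidate interval (any-overlap rule by
default; full containment optional):

1. **Co-expression** (`coexpressionNeighbors`): neighbors with mutual rank
   strictly below 50. MR(A,B) = √(rank_{A→B}·rank_{B→A}), the geometric
   mean of reciprocal Pearson-correlation ranks over the compendium
   (self excluded, ties broken by gene order) — the ATTED-II convention;
   "below 50" is a strict inequality. A band variant that additionally
   requires MR above (the gene's maximum rank − 50) — which, read
   literally, admits each gene's *weakest* partners — is implemented as an
   optional secondary filter, off by default, rather than guessing an
   intent. A candidate absent from the compendium gets
   an empty neighborhood with a warning — exactly how recently annotated
   genes missing from an array platform behave.
2. **eQTL colocalization** (`eqtlColocalizationFilter`): a neighbor is kept
   only if one of its eQTL confidence intervals overlaps the candidate's
   own gene span, turning the undirected co-expression link into a directed
   candidate → target edge. eQTL CIs follow the contiguous-interval rule
   (`eqtlCIFromScan`): the marker interval holding the peak plus one
   interval on each side (a peak on an interior marker owns both abutting
   intervals), truncated at chromosome ends. Gene coordinates are physical
   (bp), eQTL peaks genetic (cM); some bridge between the two scales is
   unavoidable, and linear interpolation between marker anchors is the
   simplest defensible one.
3. **GO coherence** (`goCoherentEdges`): an edge is coherent when source
   and target share ≥ 1 GO-Slim term of the biological-process aspect
   ("involved in"); other aspects are discarded first. Genes without GO
   annotation are never coherent — the method is blind to uncharacterized
   genes, and the suite asserts that deleting the regulator's GO rows
   removes it from the coherent ranking entirely.
4. **Polymorphism flags** (`polymorphismFlags`): a candidate is polymorphic
   if it carries a non-synonymous change between the parents *or* has a
   cis-eQTL (an eQTL of its own expression overlapping its own locus);
   both flags are stored separately, and cis-eQTLs appear as self-loop
   edges of type `cis`.
5. **Ranking** (`assembleAndRank`): candidates are ordered by coherent
   (GO-sharing) edges, with ties broken by total edges, then the
   polymorphism flag, then gene id — so the ranking itself counts
   functional connections only, and a well-connected hub outranks a
   polymorphic non-hub, with flags reported alongside. Degree-0 nodes are
   dropped from the exported graph (SIF and GraphML, Cytoscape-loadable)
   but kept in the ranking table.

GO coloring and eQTL filtering act on disjoint edge attributes, and the
suite asserts they commute.

## The synthetic generator

`simulateScenario` produces every input with planted truth:

* **Map and genotypes**: default 5 chromosomes × 116 markers × 100 cM,
  physical anchor 250 kb/cM (an *Arabidopsis*-scale genome); selfed-RIL
  mosaics under the Haldane/2r/(1+2r) transition, fair first marker,
  independent chromosomes. Empirical switch rates are asserted within 3
  binomial SE of theory at d ∈ {1, 5, 10, 20} cM over 10,000 lines.
* **Phenotypes**: plant value = treatment mean + Σ_QTL ±effect(treatment)
  + line effect N(0, lineSD²) + shade-only line deviation N(0, gxeSD²)
  + nuisance level shifts + N(0, noiseSD²). The default plants a G×E QTL
  at the regulator locus (effect 0 in sun, −1 in shade: the B allele
  accelerates development under shade, so the stronger shade-avoidance
  response segregates with the B parent) and one
  constitutive QTL (0.5/0.5) on another chromosome, which must appear in
  the single-condition scans but not the SAR scans.
* **Expression compendium**: genes × 200 experiments; module members
  (regulator + 12 targets + decoys) share a latent factor giving pairwise
  correlation ρ = 0.8; background genes independent.
* **Annotation layers**: 100 genes tiled in a 1.6 Mb window around the
  regulator (the candidate neighborhood, gene span 2 kb — roughly genic
  *Arabidopsis* densities) plus 200 background genes genome-wide; a shared
  biological-process term for the module; a non-synonymous flag and
  cis-eQTL for the regulator; target eQTLs peaked at the marker nearest
  the regulator with contiguous-interval CIs; decoy candidates
  (co-expressed without eQTL support, polymorphic without a module) for
  specificity testing; random background GO terms, polymorphisms and
  trans-eQTLs as noise.

**Why these variance defaults.** With noiseSD = 1, four replicate plants
per line and treatment, lineSD = 1 and gxeSD = 1.4, the closed-form
variance budget of the residual index gives the planted unit QTL a variance
share of ≈ 0.29 — the size of a major plasticity QTL in a RIL population,
where a single strong locus typically explains a quarter to a third of the
index variance — while keeping the two SAR
indices correlated above 0.9 and the constitutive-QTL leak (attenuation
analysis above) negligible. A model with measurement noise alone cannot
satisfy all three at once: the line-level components (polygenic background
and unmodeled plasticity variance) are what reconcile a moderate locus PVE
with high index repeatability, exactly as in real populations. These
values were fixed from this calculation, not fitted to test outcomes.

What the generator does **not** emulate: microarray normalization and probe
effects, missing expression data, epistasis, residual heterozygosity,
linkage between the expression module and the genetic background, or
realistic GO term hierarchies. Passing tests demonstrate that the
*algorithms* recover planted structure under the stated statistical model;
they are not evidence about any particular real dataset.

## Numerical conventions

* Peak ties: leftmost genome position wins.
* Permutation quantile: nearest-rank (k = ⌈q·n⌉, clamped to [1, n]).
* Mutual-rank correlation ties: broken by gene order (`ties.method =
  "first"`).
* MR cutoff: strict (< 50).
* Monomorphic scan positions (no genotype variance): LOD = a = PVE = 0.
* Support interval endpoints: outermost grid points still within the drop;
  drop = 0 gives the peak point.
* All randomness flows from one root seed through per-stage derived
  streams; equal seeds give byte-identical artifacts (asserted via file
  checksums).

## Problem sizes used by the test suite

Statistical assertions run at the following sizes, chosen as the smallest
that make the asserted rates stable: threshold calibration at 400
replicates × 1,000 permutations (n = 253); interval coverage at 200
replicates; G×E specificity at 100 replicates per arm; hub recovery and the
module-free null at 50 end-to-end runs each (200 permutations within each
run); recombination calibration at 10,000 lines. Oracle equivalences (lm
regression, brute-force mutual ranks, two-locus enumeration, GO
set-intersection) are exact to 1e-9 or better.

## Limitations

* Haley–Knott regression approximates full-likelihood interval mapping;
  the approximation is exact at complete typed markers and very close
  between markers for RILs, but is not suited to dominant markers or
  heavy missingness.
* The two-stage nuisance adjustment matches REML only for reasonably
  balanced designs.
* Composite interval mapping, multi-QTL models and epistasis are out of
  scope, as are GO enrichment statistics and protein–protein evidence
  layers.
* The ranking is only as good as the annotation: unannotated or
  unmeasured genes cannot win — an inherent blind spot of
  annotation-based coherence, deliberately preserved and tested.
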