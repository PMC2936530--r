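# sarnet — shade-avoidance QTL mapping and candidate-gene network prioritization

`sarnet` is an R package for the two-stage genetic dissection of
phenotypic plasticity in biparental recombinant inbred line (RIL)
populations, modeled on the analysis path that identifies a regulator gene
under a shade-avoidance QTL:

1. **Plasticity indices.** Plant-level phenotypes measured under simulated
   sun and shade are collapsed into per-line condition indices (with
   F-screened nuisance-factor adjustment and a Shapiro–Wilk/log normality
   gate), and into two shade-avoidance response (SAR) indices: the
   *subtraction* index (sun − shade) and the *residual* index (negated
   residuals of the regression of shade on sun indices).
2. **Interval mapping.** Haley–Knott regression on RIL genotype
   probabilities (Haldane map function, selfed-RIL transition
   R = 2r/(1+2r)) yields LOD = (n/2)·log10(RSS₀/RSS₁), the additive effect
   a = (mean_B − mean_S)/2 and the variance explained
   PVE = 1 − 10^(−2·LOD/n), with genome-wide significance thresholds from
   permutations and 2-LOD support intervals anchored to physical
   coordinates. An informative-subset selector re-scans random line
   subsets to maximize the effect at a target locus.
3. **Candidate network.** For every gene in the support interval:
   co-expression neighbors at mutual rank < 50 (MR(A,B) =
   √(rank_{A→B}·rank_{B→A}) over an expression compendium), filtered to
   neighbors whose eQTL confidence interval (peak marker interval ± one
   contiguous interval) overlaps the candidate's locus, colored by shared
   GO-Slim biological-process terms, flagged for non-synonymous
   polymorphisms and cis-eQTLs (self-loops), and ranked by the number of
   functionally coherent connections. Exports are Cytoscape-loadable (SIF,
   GraphML).

A fully seeded synthetic-data generator produces every input (genetic map,
RIL genotypes, G×E phenotypes, expression compendium with a planted
regulator module, annotation/GO/polymorphism/eQTL layers with decoys) so
the entire pipeline is testable end to end with planted ground truth. See
the vignette in `vignettes/shade-avoidance-qtl-networks.Rmd` for the model,
parameter defaults and design decisions.

## Worked example

One seeded end-to-end run — simulate a 253-line population (5 chromosomes ×
116 markers), compute indices, scan all four indices, take the 2-LOD
interval on the residual SAR index and rank the candidates:

```r
library(sarnet)
rep <- runPipeline(pipelineConfig(), seed = 1)
print(rep)
#> sarnet pipeline report (seed 1)
#>   flowering_time_sun             peak chr4 @  51.3 cM  LOD  12.63  a +0.547  PVE 20.5%
#>   flowering_time_shade           peak chr2 @  40.0 cM  LOD  15.89  a -1.111  PVE 25.1%
#>   flowering_time_subtraction     peak chr2 @  40.0 cM  LOD  22.87  a +1.123  PVE 34.1%
#>   flowering_time_residual        peak chr2 @  40.0 cM  LOD  22.89  a +1.122  PVE 34.1%  (threshold 2.83)
#>   interval: chr2 39.0-40.0 cM (9750000-10000000 bp)
#>   top candidate: g2_00106 (12 coherent / 12 edges)
#>   ground truth: regulator g2_00106, rank 1, in interval: TRUE

head(rep$ranking, 5)
#>    gene_id n_coherent_edges n_edges polymorphic rank
#> 1 g2_00106               12      12        TRUE    1
#> 2 g2_00100                4       4       FALSE    2
#> 3 g2_00097                1      10       FALSE    3
#> 4 g2_00095                1       5        TRUE    4
#> 5 g2_00105                1       5       FALSE    5
```

Reading the report: the constitutive QTL planted on chromosome 4 dominates
the *sun* scan but vanishes from both SAR indices, while the planted G×E
QTL on chromosome 2 (effect only under shade) is the single SAR peak — its
positive additive effect means the B parental allele strengthens the
response. The residual index explains ~34% of the variance at the peak,
the genome-wide 5% LOD threshold from 1,000 permutations is 2.83, and the
2-LOD interval spans 250 kb. Inside it, the planted regulator `g2_00106`
is ranked first with all 12 of its planted targets recovered as coherent
edges; the runner-up picks up a handful of coincidental connections.
Passing `outdir =` writes every stage artifact (map/genotype CSV, index and
scan TSVs, threshold JSON, interval BED, annotation GFF3, network
SIF/GraphML, ranking TSV, report JSON), byte-identically for a fixed seed.

A thin command-line wrapper over the same functions supports stage-wise
runs (`simulate`, `indices`, `scan`, `network`, `report`, `all`):

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/sarnet-pipeline.R", package="sarnet"))') \
    all --seed 1 --outdir run1
```

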