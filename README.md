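# ssrpop

Genetic diversity and population structure analysis for codominant
microsatellite (SSR) genotypes, written for plant-genetic-resource studies:
collections of accessions genotyped at a small SSR panel, with a population
(collection zone) label per individual. From a table of fragment-size calls,
ssrpop computes the full report stack such studies publish:

- **Per-marker diversity** — major allele frequency, allele number, gene
  diversity `GD = 1 − Σpᵢ²`, Botstein's
  `PIC = 1 − Σpᵢ² − Σᵢ<ⱼ 2pᵢ²pⱼ²`, observed heterozygosity, with the
  conventional Mean/Max/Min table rows and informativeness grades.
- **Per-population allelic patterns** — Na, Na at frequency ≥ 5 %, effective
  alleles `Ne = 1/Σpᵢ²`, Shannon's `I = −Σpᵢ ln pᵢ`, private and locally
  common alleles, `He`, unbiased `uHe = 2N/(2N−1)·He`, fixation index
  `F = 1 − Ho/He`.
- **F-statistics and gene flow** — per locus over all populations,
  `Fis = (H̄e − H̄o)/H̄e`, `Fit = (Ht − H̄o)/Ht`, `Fst = (Ht − H̄e)/Ht`,
  `Nm = ((1/Fst) − 1)/4`; pairwise population Fst, Nei genetic distance
  (1972 standard and 1978 unbiased), pairwise Nm, interpretation grades.
- **AMOVA** — two-level analysis of molecular variance on the codominant
  squared genotypic distance (case values 0/1/2/3/4 per locus), with a
  permutation test.
- **Ordination and trees** — principal coordinates with axis percentages,
  and a deterministic UPGMA dendrogram (shared-allele or squared genotypic
  distance) with Newick export.
- **Bayesian admixture clustering** — a Gibbs sampler for the
  STRUCTURE-family admixture model with correlated allele frequencies
  (compiled C++ core, fully seed-deterministic), `ln P(D)` estimation,
  label alignment across runs, and Evanno ΔK selection of the number of
  clusters.
- **A synthetic SSR generator** — Balding–Nichols population frequencies
  with controllable differentiation, selfing (autozygosity), admixture and
  missingness, so every statistic above can be verified against known truth.

Functions are tibble-first and pipe-friendly; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(ssrpop)

# a synthetic collection: 91 accessions, 5 zones, 13 SSR loci,
# strong selfing (Fis 0.79) and moderate differentiation
sim <- simulate_ssr(ssr_sim_spec(seed = 1))
g   <- sim$genotypes
g
#> <ssr_genotypes> 91 individuals x 13 loci, 5 populations, 0 missing calls

locus_summary(g)
#> # A tibble: 13 × 7
#>   locus   maf     n n_alleles   pic     ho gene_diversity
#> 1 L01   0.313    91         9 0.760 0.143           0.788
#> 2 L02   0.253    91        10 0.804 0.198           0.827
#> ...

per_locus_fstats(g) |> add_summary_rows(digits = 2) |> tail(3)
#>   locus    ht mean_he mean_ho   fis   fit   fst    nm
#> 1 Mean   0.79    0.62    0.14  0.76  0.82  0.22  1.03
#> 2 Max    0.87    0.76    0.26  0.9   0.91  0.31  1.87
#> 3 Min    0.62    0.43    0.07  0.63  0.7   0.12  0.56

run_amova(individual_squared_distances(g), pop_table(g),
          n_perm = 999, seed = 2)
#> Analysis of molecular variance
#>       source df     SS    MS variance percent
#>   Among Pops  4  283.2 70.79    3.564   18.41
#>  Within Pops 86 1357.9 15.79   15.789   81.59
#>        Total 90 1641.0    NA   19.353  100.00
#> Among-population p-value: 0.001 (999 permutations)
```

Read this as a field geneticist would: the mean per-locus `Fis` of 0.76
confirms the heavy homozygote excess of a selfing crop, mean `Fst` 0.22
grades as high differentiation while mean `Nm` ≈ 1 still indicates gene
flow, and the AMOVA places ~82 % of molecular variance within zones — the
among-zone share (18 %) is significant at p = 0.001.

Real data enters through `read_genotypes()` (GenAlEx codominant CSV or a
long `id,pop,locus,a1,a2` table; gel sizes can be binned with
`bin_alleles()`), and `run_pipeline()` writes the entire report bundle
(tables, Newick tree, PCoA coordinates, admixture Q matrix, Evanno table,
JSON summary, run log) in one call — or from a shell:

```sh
Rscript scripts/run_pipeline.R --input genotypes.csv --dialect genalex \
  --out results/ --seed 1
```

The package also bundles a published 13-marker sweet sorghum reference
panel (`ssr_panel()`): marker metadata and its per-marker diversity and
F-statistic tables, used as worked-example input for consistency checks.

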