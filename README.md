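# ecoassembly

Null-model inference of the ecological processes that assemble microbial
communities, for 16S/ASV surveys of plant and soil microbiomes.

Given an ASV count table, a rooted phylogeny over the ASVs and sample
metadata (farm, niche, health status, coordinates, soil chemistry), the
package classifies every within-group pair of communities into one of
five assembly processes and reports per-group process fractions, along
with the supporting diversity and association analyses such a survey
needs: Hill-number alpha diversity under repeated rarefaction,
Bray–Curtis and weighted UniFrac distances, PCoA, PERMANOVA and
dispersion tests, core-taxon detection, phylum–chemistry correlations,
ENS–chemistry regressions, and Mantel tests against geographic and soil
chemistry distances. A synthetic-study generator produces complete seeded
datasets with known assembly regimes, so the whole pipeline is testable
without any sequencing data.

## The statistics at the core

For a pair of communities, the beta mean nearest taxon distance

βMNTD = ½ Σᵢ∈ₖ fᵢ · minⱼ∈ₘ d(i,j) + ½ Σⱼ∈ₘ fⱼ · minᵢ∈ₖ d(i,j)

(patristic distances d, within-sample relative abundances f) is
standardized against a null distribution obtained by shuffling taxon
identities across the tips of the pooled phylogeny:
βNTI = (obs − μ₀)/σ₀. Pairs with βNTI ≥ 2 are classified as
heterogeneous selection, ≤ −2 as homogeneous selection. The remaining
pairs are split by the Raup–Crick metric on Bray–Curtis, RC ∈ [−1, 1],
whose null re-assembles each sample from the species pool (richness drawn
by occupancy, reads filled by pool abundance): RC ≥ 0.95 → dispersal
limitation with drift, RC ≤ −0.95 → homogenizing dispersal, otherwise
drift. Null loops are compiled (Rcpp) and fully seeded.

## Worked example

Simulate a two-group study in which healthy-farm communities are
assembled by environmental filtering (selection) and unhealthy-farm
communities are neutral, then recover those processes:

```r
library(ecoassembly)

scenario <- synthetic_scenario(n_taxa = 600, n_farms = 6,
                               niches = "rhizosphere_soil",
                               samples_per_group = 10, regime = "mixed",
                               depth_mean = 1000, seed = 11)
study <- generate_dataset(scenario)

result <- assembly_analysis(study$table, study$tree, study$meta,
                            config = null_model_config(n_reps = 999, seed = 11,
                                                       pool_scope = "all_samples"))
head(result$pairs[, c("sample_i", "sample_j", "bnti", "rc_bray", "process")], 4)
#>   sample_i sample_j  bnti rc_bray                process
#> 1     S001     S002 -1.47  -0.986 homogenizing_dispersal
#> 2     S001     S003 -3.20  -0.921  homogeneous_selection
#> 3     S001     S004 -1.36  -0.986 homogenizing_dispersal
#> 4     S001     S005 -1.98  -0.877                  drift

subset(result$fractions, fraction > 0)
#>                         group                    process fraction n_pairs
#> 2    rhizosphere_soil:healthy      homogeneous_selection    0.511      45
#> 4    rhizosphere_soil:healthy     homogenizing_dispersal    0.378      45
#> 5    rhizosphere_soil:healthy                      drift    0.111      45
#> 7  rhizosphere_soil:unhealthy      homogeneous_selection    0.022      45
#> 8  rhizosphere_soil:unhealthy dispersal_limitation_drift    0.911      45
#> 10 rhizosphere_soil:unhealthy                      drift    0.067      45
```

The healthy group — generated under a shared environmental filter — is
dominated by deterministic classes (51% homogeneous selection), while the
neutrally assembled unhealthy group is almost entirely stochastic (98%
dispersal limitation + drift). Alpha diversity and distance–decay follow
the same objects:

```r
alpha_diversity(study$table, depth = 500, n_draws = 50, seed = 11)[1:3, ]
#>   sample_id    ens            mode rarefaction_depth n_rarefactions
#> 1      S001  8.143 inverse_simpson               500             50
#> 2      S002  7.461 inverse_simpson               500             50
#> 3      S003 10.495 inverse_simpson               500             50

dgeo <- geographic_distance_matrix(study$meta, level = "sample")
dbc  <- bray_curtis_matrix(to_relative(study$table))
mantel_test(dbc, dgeo, n_permutations = 999, seed = 11)[c("statistic", "p_value")]
#> $statistic
#> [1] 0.1699324
#> $p_value
#> [1] 0.024
```

ENS here is the inverse-Simpson Hill number: e.g. S001's community
behaves like ~8 equally abundant taxa at a rarefaction depth of 500
reads. The Mantel statistic (0.17, p = 0.024) reflects the distance decay
the farm-local pools induce. `run_pipeline(run_config(...))` executes the
whole battery (harmonization → diversity → assembly → core taxa →
correlations → Mantel) from files on disk and writes TSV tables plus a
JSON manifest recording every seed, threshold and assumption;
`inst/scripts/ecoassembly.R` is a command-line wrapper with `simulate`
and `run` subcommands.

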