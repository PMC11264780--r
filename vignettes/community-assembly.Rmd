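---
title: "Quantifying community assembly processes with ecoassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly processes with ecoassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

## The question the package answers

Plant-associated bacterial communities are shaped by a mixture of
deterministic processes (environmental selection by soil chemistry, host
physiology, niche) and stochastic ones (dispersal, ecological drift).
`ecoassembly` quantifies that mixture from three inputs a 16S amplicon
survey produces anyway: an ASV count table, a rooted phylogeny over the
ASVs, and sample metadata (farm, niche, health status, coordinates, soil
chemistry). Its design mirrors a multi-farm strawberry microbiome survey
(13 organic farms in south-east Poland, four niches — bulk soil,
rhizosphere soil, root, shoot — and a healthy/unhealthy status per farm),
but nothing in the code is specific to that crop.

The headline statistic is the pairwise classification of community
turnover into five assembly processes, obtained from two null models.

## The null models

**betaMNTD and betaNTI.** For two communities $k$ and $m$, the beta mean
nearest taxon distance is

$$\beta\mathrm{MNTD} = \tfrac12 \sum_{i \in k} f_i \min_{j \in m} d_{ij}
                     + \tfrac12 \sum_{j \in m} f_j \min_{i \in k} d_{ij},$$

where $d_{ij}$ is the patristic distance between taxa and $f_i$ the
relative abundance of taxon $i$ within its sample (uniform weights in the
unweighted form). Its standardized effect size, betaNTI, compares the
observed value against a null distribution obtained by shuffling taxon
identities uniformly at random across the tips of the pooled tree —
equivalently, jointly permuting rows and columns of the patristic matrix —
and recomputing betaMNTD each time:
$\beta\mathrm{NTI} = (\mathrm{obs} - \mu_0)/\sigma_0$. One shuffle per
replicate is shared by all pairs; 999 replicates by default. betaNTI below
$-2$ indicates phylogenetically clustered turnover (homogeneous
selection), above $+2$ phylogenetically overdispersed turnover
(heterogeneous, or variable, selection).

**RC-bray.** For pairs not dominated by selection, the Raup–Crick metric
on Bray–Curtis dissimilarity asks whether the two communities are more or
less similar than expected under random assembly from the species pool.
Each replicate assembles a null version of every sample: the sample's
observed richness is drawn without replacement with probability
proportional to taxon occupancy in the pool, and its observed read total
is then distributed multinomially over the drawn taxa proportional to
pool-wide relative abundances, with at least one read per drawn taxon so
the drawn richness is realized. With $n$ the number of replicates,

$$RC = 2\,\frac{\#\{BC_{null} < BC_{obs}\} + \tfrac12\#\{BC_{null} = BC_{obs}\}}{n} - 1
\in [-1, 1].$$

Null communities are drawn once per sample per replicate and all pairwise
Bray–Curtis values computed from that replicate's cohort; each pair still
receives `n_reps` independent null values, and the within-pair null
distribution is identical to drawing per pair, at a fraction of the cost.

**Classification.** With default thresholds $t_b = 2$, $t_r = 0.95$:
betaNTI $\ge t_b$ → heterogeneous selection; $\le -t_b$ → homogeneous
selection; otherwise RC $\ge t_r$ → dispersal limitation with drift;
RC $\le -t_r$ → homogenizing dispersal; else drift. Threshold values
sitting exactly on a boundary resolve toward the non-drift category, a
convention chosen because strict inequalities would leave the boundary
undefined. Pairs whose betaNTI null standard deviation is zero (e.g. two
samples with identical taxon support) are flagged undefined and excluded
from the per-group process fractions.

### The species pool matters

`null_model_config(pool_scope =)` controls which samples define the pool
the nulls draw from. `"group"` (the default) pools each niche × health
stratum, matching the per-group reporting of process fractions.
`"all_samples"` uses the whole table as a regional pool. The choice is
consequential: homogeneous selection is *clustering relative to the
pool*, so if every sample in the pool passed the same environmental
filter, the pool collapses onto the selected clade and the signal is
absorbed — betaNTI hovers near zero no matter how strong the filter was.
Detecting homogeneous selection therefore requires a pool broader than
the filtered group (other niches, statuses, or habitats). This is a
property of the method, not an implementation choice; the package's own
recovery tests use the regional pool for the selection scenario for
exactly this reason, and users analysing a single homogeneous stratum
should expect conservative betaNTI values.

## Diversity and distance analyses

Alpha diversity is reported as the effective number of species. The
default mode is the inverse Simpson concentration (Hill number of order
2): for the uniform community of $S$ species it equals $S$, which is the
defining property of an effective number. The literal reading
"exponential of the Simpson index", $\exp(1 - \sum p_i^2)$, is bounded by
$e$ and cannot reach $S$; it is retained as mode
`"exp_simpson_literal"` for comparability but flagged by its name.
Repeated rarefaction (default 100 draws, depth = the smallest retained
sample total within the stratum) computes ENS per draw and averages;
samples below the depth are dropped and reported.

Bray–Curtis and weighted UniFrac distances feed PCoA, PERMANOVA and the
betadisper-style dispersion test. Weighted UniFrac is computed directly
from branch-wise abundance proportions by postorder accumulation (raw
form $\sum_b \ell_b |p_A(b) - p_B(b)|$; normalized form divides by
$\sum_b \ell_b (p_A(b) + p_B(b))$) and is cross-checked against
`phyloseq::UniFrac` in the test suite. PCoA reports negative eigenvalues
and excludes them from the explained-variance denominator, the common
convention for two-axis percent-explained labels. PERMANOVA and the
dispersion test permute sample labels freely (no strata), matching a
single-factor design, with $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n)$;
both accept an explicit permutation matrix so small designs can be tested
by complete enumeration.

Associations with the environment use Spearman correlations of
phylum-level relative abundances against soil chemistry
(Benjamini–Hochberg adjusted within each niche × health stratum across
all phylum × variable tests — the correction family is a package choice,
recorded in the output), ordinary least squares of ENS on single
chemistry variables (slope, adjusted $R^2$, two-sided slope $p$), and
Mantel tests of community dissimilarity against great-circle
(haversine, Earth radius 6371 km) and z-scored Euclidean chemistry
distances between farms, expanded to sample level by farm membership.
Mantel defaults to Pearson with a one-sided "greater" alternative, the
distance-decay convention. Core taxa require joint prevalence
(default ≥ 95% of the group's samples) and mean relative abundance
(default ≥ 0.1%); both comparisons are inclusive, so boundary cases
qualify, and an alternative per-sample abundance mode is available.

Missing chemistry values propagate as `NA` and are dropped pairwise by
correlations and regressions; farm-level values are shared by a farm's
samples.

## The synthetic study generator

`generate_dataset()` produces a complete, fully seeded study: a Yule tree
rescaled to unit depth, Brownian traits (variance $\sigma^2 \times$
branch length), farm coordinates jittered within half a degree of
50°N 23°E, soil chemistry linked to a latent environmental axis
(pH and Mg carry the signal with residual sd 0.3; P2O5, K2O and organic
carbon are independent lognormals), and communities assembled per
niche × health group under a known regime. Defaults emulate the
motivating design: 13 farms split 7/6 into healthy/unhealthy (health is a
farm-level attribute), four niches, 20 samples per group, mean depth
5000 reads with lognormal variation, and a metacommunity (default 1000
taxa) much richer than any one sample — the regime in which amplicon
surveys operate and in which nearest-taxon statistics are informative.

The three regimes realize the processes the classifier should recover:

* **Selection** — sampling weights
  $\propto \mathrm{pool}_i \times \exp(-(x_i - e)^2 / 2\sigma_{sel}^2)
  \times \exp(\varepsilon_i)$, where $x_i$ is the taxon's trait, $e$ the
  group's optimum and $\varepsilon_i \sim N(0, \mathrm{lottery\_sd}^2)$ a
  per-sample competitive-lottery term. The lottery term is essential:
  without it, samples under one filter are near-replicate multinomials
  whose only turnover is the filter's edge, and no clustering signal
  reaches betaNTI. With it, samples share the suitable clade but differ
  in which members dominate — the classic lottery picture of selection
  plus demographic stochasticity. Optima sit in opposite tails of the
  trait distribution for the two health statuses
  (±`env_health_shift`/2 trait sd), so each status filters a deep clade
  and the statuses diverge; strong filtering uses
  $\sigma_{sel} = 0.2 \times$ trait sd.
* **Drift** — self-consistent random placement. A neutral sample draws
  its richness, places taxa with probability proportional to an occupancy
  vector, and fills reads proportional to pool abundances with one read
  per placed taxon — the same recipe as the RC null. The occupancy and
  fill vectors are computed as a fixed point of that recipe
  (`neutral_placement_stats()`, four calibration iterations): statistics
  measured on assembled cohorts equal the statistics used to assemble
  them. A plain multinomial would *not* be neutral in the Raup–Crick
  sense — replicate multinomials share every abundant taxon and are
  systematically more similar than random assemblies, which reads as
  homogenizing dispersal. Genuine drift requires identity as well as
  abundance turnover.
* **Dispersal limitation** — each farm receives a uniform random subset
  (fraction `m`, default 0.2) of the metacommunity as its local pool,
  shared by its samples, with neutral multinomial draws inside it. The
  draw is uniform, not abundance-weighted: weighting by abundance would
  place the same dominant taxa in every farm and erase precisely the
  between-farm compositional signature that dispersal limitation creates.

`regime = "mixed"` assigns selection to healthy groups and drift to
unhealthy ones, giving one dataset that exercises every classifier
branch.

### What the generator does and does not emulate

It reproduces the study's *shape* — design, farm-level chemistry and
coordinates, depth variation, phylogenetically structured communities
with known assembly regimes — at desk scale (hundreds to a couple of
thousand taxa rather than 55,000 ASVs). It does not simulate reads,
chimeras, taxonomic misassignment, compositional sequencing artifacts, or
temporal dynamics. Passing recovery tests therefore demonstrates that the
statistical machinery identifies the processes that generated clean,
structured data of realistic shape; it does not validate robustness to
upstream bioinformatic error.

## Numerical and design choices

* Null replicates default to 999; permutation p-values use the
  add-one convention, so $p \ge 1/(n+1)$.
* betaNTI and RC engines are compiled (Rcpp). The betaMNTD null loop
  computes, per replicate, each pool taxon's nearest-taxon distance to
  every sample once — $O(\text{samples} \times \text{taxa} \times
  \text{richness})$ per replicate rather than pairs × richness².
  Weighted draws use exponential keys, distributionally identical to
  sequential weighted sampling without replacement. All randomness flows
  through R's RNG, so a `seed` reproduces results bit for bit.
* RC equality ties (observed BC exactly equal to a null value) count
  half, with a $10^{-10}$ tolerance.
* Rarefaction subsamples without replacement via `vegan::rrarefy`;
  identical seeds give identical draws.
* Degenerate inputs fail loudly: all-zero sample pairs in Bray–Curtis,
  zero-variance predictors in regressions and chemistry z-scores,
  constant distance matrices in Mantel tests, empty id intersections in
  `harmonize()`.
* `harmonize()` is idempotent; branch lengths absent from a newick file
  become zero with a warning; ids are whitespace-trimmed but
  case-sensitive.

### Choices of problem size in the validation suite

The package's own tests run the recovery scenarios at sizes chosen so the
signal each scenario encodes is identifiable: selection uses a 1500-taxon
metacommunity at depth 300 (pool ≫ richness, as in real surveys — with a
saturated pool the null nearest-neighbour distances collapse and no
clustering is detectable), drift uses 300 taxa at depth 1000 with 16
samples per group (120 within-group pairs), dispersal uses 600 taxa with
m = 0.2 across 6 farms. betaNTI self-calibration aggregates twelve
independent 50-taxon, 12-sample tip-shuffled tables: pairs within one
table share a single observed tip assignment and are strongly correlated,
so the pooled 792 pairs — not the 66 of a single table — are what make
the mean/sd/tail-fraction summaries stable.

## Known limitations

* betaNTI requires a phylogeny; the motivating study does not state how
  (or whether) one was built, so the package requires a user-supplied or
  synthetic tree and treats its quality as the user's responsibility.
* With `pool_scope = "group"` and an ecologically uniform stratum,
  homogeneous selection is structurally hard to detect (see above).
* The RC null conditions on observed richness and total reads; it does
  not model overdispersion beyond the multinomial, so heavily
  zero-inflated data may sit systematically inside or outside the null
  envelope.
* The replicate count, pool definition and abundance weighting used by
  the motivating study are unstated; the defaults here (999 replicates,
  group pools, abundance-weighted betaMNTD) are recorded in every output
  manifest so downstream comparisons can see the assumptions.
* "Variable selection" in parts of the ecological literature is used
  synonymously with heterogeneous selection; the package uses the label
  `heterogeneous_selection` throughout.
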