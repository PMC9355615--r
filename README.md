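# guildassembly

Community-assembly inference for soil fungal functional guilds.

Soil fungi assemble under a mix of deterministic processes (environmental
selection by edaphic conditions and plant attributes) and stochastic ones
(dispersal limitation, drift).  `guildassembly` implements the
abundance-weighted **β-null deviation** approach for quantifying that
balance, applied separately to the total fungal community and to its
FUNGuild-derived functional guilds (mycorrhizal, saprotrophic,
pathotrophic), together with the distance-matrix statistics used to
attribute the deviations to plant, edaphic and spatial drivers.  It is
aimed at microbial ecologists working with site-by-OTU count tables from
amplicon surveys, and ships a synthetic-community generator with known
assembly regimes so every statistic can be validated against ground truth.

## The statistic

For a rarefied table, the regional species-abundance distribution is fixed
at the observed column totals.  Null communities redraw each sample's
N_i individuals multinomially from that pool, preserving per-sample
abundance.  For each sample pair (i, j):

    ses(i, j) = ( BC_obs(i, j) − mean_null BC(i, j) ) / sd_null BC(i, j)

where BC is Bray–Curtis dissimilarity, Σ|x_ik − x_jk| / Σ(x_ik + x_jk), and
the null moments come from `n_null` (default 999) replicates.  Mean ses ≈ 0
indicates stochastic assembly; ses > 0 divergence beyond chance
(heterogeneous selection or dispersal limitation); ses < 0 convergence
(homogeneous selection or homogenizing dispersal).  A `raw` mode
(observed − null mean, bounded in [−1, 1]) is also available.

Attribution then uses Mantel and partial Mantel tests, multiple regression
on distance matrices (MRM) with forward selection at P < 0.05, and
variation partitioning whose pure environmental fraction is read as
selection and pure spatial fraction as dispersal limitation; PERMANOVA/NMDS
summarize compositional structure, and quantile-category contrasts
(Wilcoxon rank-sum with compact letter display) track how deviations shift
along gradients of community-weighted specific root length (SRL) or
fine-root biomass (FRB).

## Worked example

```r
library(guildassembly)

pool <- simulate_pool(n_otus = 300, lognormal_sigma = 1.5, seed = 1)
scenario <- assembly_scenario("heterogeneous_selection",
                              n_sites = 10, quadrats_per_site = 1,
                              depths = "surface", reads_per_sample = 2000,
                              niche_breadth = 0.1, seed = 1)
ds <- assemble_communities(pool, scenario)

bd <- beta_deviation(ds$otu_table, n_null = 999, seed = 1)
mt <- mean_deviation_test(bd)

md  <- apply_transforms(ds$metadata)
tr  <- apply_transforms(ds$trait_table)
cwm <- community_weighted_mean(ds$plant_community, tr, "SRL")
srl_d   <- standardized_euclidean_1d(setNames(cwm[md$quadrat_id], md$sample_id))
space_d <- geographic_distance(md)
mantel(srl_d, bd$deviation, n_perm = 999, seed = 2)
forward_select_mrm(bd$deviation, list(SRL = srl_d, space = space_d),
                   n_perm = 999, seed = 3)
variation_partitioning(bd$deviation, list(SRL = srl_d), list(space = space_d))
```

prints

```
beta-null deviation: 10 samples, 999 nulls, mode = ses
  mean deviation: 46.1108 (range -10.1036 .. 97.0635, 0 flagged cells)
mean ses = 46.11, t = 9.26, p = 6.72e-12
Mantel CWM-SRL vs ses: r = 0.916, p = 0.001
MRM selected: SRL; R2 = 0.839
VPA: pure env 0.839, pure space 0.000, shared 0.001, unexplained 0.161
```

Read: communities diverge far beyond the null expectation (mean ses ≫ 0 —
heterogeneous selection), the divergence tracks the root-trait gradient
(Mantel r = 0.92; MRM keeps SRL with 84% of variance explained), and
essentially none of it is attributable to space — exactly the regime the
generator was told to produce.

## Pipeline and CLI

One JSON config drives the whole analysis per depth-layer × guild stratum
(`run_pipeline()`, or the `inst/exec/guildassembly` script):

```sh
guildassembly run --config config.json --out-dir out/
guildassembly simulate --regime neutral --seed 1 --out-dir sim/
guildassembly betadev --otu-table otu.tsv --n-null 999 --seed 1 --out-dir bd/
```

Config keys: either `simulate` (an `assembly_scenario()` argument list plus
`n_otus`, `lognormal_sigma`) or `inputs` (paths: `otu_table`, `annotation`,
`metadata`, `plant_community`, `trait_table`), plus `n_null` (999), `n_perm`
(999), `alpha` (0.05), `mode` (`ses`), `rarefy_depth` (`auto`),
`depth_layers`, `guilds`, `seed`.  See
`inst/extdata/example_config.json`.  Outputs per stratum: signed deviation
matrix TSV, Mantel/partial-Mantel tables, MRM + VPA + PERMANOVA summary
JSON, NMDS coordinates, category contrasts, plus a manifest and Markdown
report; reruns with the same config and seed are byte-identical.

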