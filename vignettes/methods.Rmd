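---
title: "Methods: beta-null deviation and assembly attribution for fungal guilds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-null deviation and assembly attribution for fungal guilds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`guildassembly` asks, for a site-by-OTU count table, whether community
turnover exceeds, matches, or falls short of what random assembly from the
regional species pool would produce — and then which measured gradients the
excess (or deficit) tracks.

**Null model.** The regional abundance distribution is fixed at the observed
table's column totals, normalized to probabilities.  Each of `n_null`
(default 999) null communities redraws every sample's observed total
multinomially from those probabilities: an abundance-weighted,
individual-based null that preserves per-sample abundance but not richness.
We chose individual resampling over richness-constrained swap algorithms
because the statistic is abundance-weighted Bray–Curtis and the null is
described as resampling individuals into local communities; the regional
pool is estimated within each analysis stratum (depth layer × guild table),
matching the stratified analysis.

**The deviation.** For each sample pair, the default `ses` mode reports
(observed − null mean) / null sd of Bray–Curtis.  The `raw` difference
(bounded in [−1, 1]) is retained as an option.  `ses` is the default
because reported mean deviations of real fungal data sets are of order
10²–10³, which is impossible for a raw Bray–Curtis difference and is the
signature of a standardized effect size; this is the single most
consequential interpretation choice in the package and is echoed in output
metadata (`mode` field, manifest `mode_note`).  Cells whose null sd is zero
(e.g. single-OTU tables) are undefined in `ses` mode; they are set to `NA`,
listed in `flagged`, and masked from all downstream triangle statistics —
never turned into infinities.

**Interpretation.** Mean ses ≈ 0: stochastic assembly.  Mean ses > 0:
divergence beyond chance — heterogeneous selection or dispersal limitation.
Mean ses < 0: convergence — homogeneous selection or homogenizing
dispersal.  The two positive-signal processes are separated downstream by
variation partitioning: pure effects of environmental/biotic predictors are
read as selection, pure effects of spatial distance as dispersal
limitation.

**The mean test.** `mean_deviation_test()` performs the field's
conventional one-sample two-sided t-test treating lower-triangle pairwise
deviations as observations.  Pairs sharing a sample are positively
correlated (each sample's multinomial realization enters n−1 pairs), so
this test is anti-conservative: on data generated by the exact null process
it rejects at α = 0.01 roughly 30% of the time in our acceptance runs, and
the result carries an explicit caveat.  `by = "samples"` aggregates to
per-sample mean deviations first, which is markedly better calibrated
though still approximate.  The pairwise default is kept because it is the
reporting convention the package mirrors; treat its p-values as
descriptive.

## Guild partitioning

FUNGuild-style records are included only when confidence is *Highly
Probable* or *Probable* and the trophic mode names a single mode (the `-`
separator marks multi-mode records); endophytes are excluded as
ambiguous.  Mycorrhizal = guild string contains "Arbuscular Mycorrhizal" or
"Ectomycorrhizal" (case-insensitive substring — FUNGuild capitalization
varies); saprotrophic/pathotrophic key on the trophic mode.  Mycorrhizal
classification keys on the guild string, not the mode, because the two
mycorrhizal guilds sit inside Symbiotroph alongside guilds (e.g.
lichenized) that we retain in the total table but assign to no guild —
a documented open choice, flagged for sensitivity analysis.

## Distance matrices and transforms

Skewed field variables are square-root (SM, SEC, SAP, NH4N, NO3N) or log10
(LA, SLA, RL, SRL, RNC) transformed before analysis; single attributes
become standardized Euclidean distances |z_i − z_j| (sample sd, n−1).
Community-weighted means, CWM = Σ P_n · Trait_n, are computed on
analysis-scale (transformed) trait values by default, so attribute distance
matrices live on the same scale as the regression variables; computing CWM
on raw traits is possible by skipping the transform.  Spatial distance is
great-circle (haversine, 6371-km sphere) in km from decimal-degree WGS84
coordinates — a planar approximation on degrees would distort N–S vs E–W at
basin scale, and km units make dispersal-decay parameters interpretable.

## Permutation inference

All matrix statistics share one canonical lower-triangle vectorization in a
fixed label order, and one permutation scheme: simultaneous row/column
permutation of the response matrix only, predictors fixed (the Legendre
convention — it preserves the predictors' correlation structure).
Monte-Carlo p-values use (count + 1)/(n_perm + 1) smoothing so p ≥
1/(n_perm + 1); `exact = TRUE` enumerates all n! permutations for n ≤ 8 and
reports the unsmoothed enumeration fraction (identity included).  Mantel
tests are two-sided on |r| by default (signed r values are reported with
significance in the literature this mirrors); one-sided remains an option.
Tie comparisons use a 1e-12 tolerance.

MRM z-scores response and predictor triangles, so coefficients are
standardized; per-coefficient statistics are |b| and the whole-model
statistic is R².  Forward selection adds, at each step, the candidate with
the largest R² gain whose marginal permutation p (within the model
containing already-selected terms) is below α = 0.05, ties broken by
candidate name order; α ≥ 1 is the documented degenerate threshold at which
every candidate enters in gain order.  Variation partitioning uses plain R²
by default (adjusted R² is available but can produce small negative pure
fractions, a confusing default); its four fractions sum to 1 by
construction, and predictors exactly collinear across the env/space groups
are pruned from the full fit so the degenerate env ≡ space case resolves to
pure shared variance.

Two honesty notes surfaced by testing.  First, for perfectly separated
groups PERMANOVA's attainable p floor is *above* 1/(n_perm + 1): label
permutations that preserve the partition reproduce the observed pseudo-F
exactly and are counted as ties under ≥-counting.  Second, permutation p
uniformity holds only marginally per test; the Mantel calibration test
checks it with a Kolmogorov–Smirnov bound.

NMDS delegates to vegan's engine (k = 2, 20 random starts, stress-1,
convergence at stress change < 1e-6) — a mature implementation we saw no
reason to duplicate; determinism is provided by seeding the start
generator.  Category contrasts bin samples by quantiles of the
(transformed) attribute — terciles or a median split — and a pairwise
deviation enters a bin only when *both* samples fall in it; bins with fewer
than two within-bin pairs are excluded and flagged.  The compact letter
display uses insert-and-absorb over the significant-pair graph.

## The synthetic generator: what it emulates and what it does not

The generator mirrors a nested arid-basin survey: 27 sites × 3 quadrats ×
2 depth layers = 162 samples by default, sites uniform on a ~100 km
rectangle, quadrats jittered ~500 m, one latent environmental axis standing
in for the river-distance/groundwater gradient, a lognormal regional
abundance distribution (σ = 1.5, the standard species-abundance model),
FUNGuild-like annotations with saprotrophs most numerous (defaults 19%
saprotrophic, 10% mycorrhizal, 5% pathotrophic of OTUs, matching observed
guild richness ordering), edaphic covariates on field-plausible scales
driven by the axis, and a 15-species plant community whose species optima
span the axis so community-weighted SRL tracks the same filter the fungi
feel (species-level trait–optimum correlation `trait_env_r`, default 0.8 —
linear coupling, chosen so recovery tests can dial effect size).
`reads_per_sample` defaults to 23,883, the rarefaction depth of the survey
design it emulates; tests use smaller worlds (typically 10 sites × 2,000
reads) purely for speed.

Regimes map to sampling probabilities over the pool: `neutral` uses
regional abundances unchanged; `heterogeneous_selection` multiplies them by
a Gaussian filter exp(−(env − optimum)²/2σ²) with per-site environments
spread over the gradient (`niche_breadth` σ, axis units, default 0.15 of a
unit gradient); `homogeneous_selection` applies the same filter at one
shared environment; `dispersal_limitation` multiplies by
exp(−`dispersal_decay` × km to an OTU-specific origin site) (default
0.05 km⁻¹, e-folding ≈ 20 km — plausible for soil fungi at basin scale and
a placeholder, since inter-site spacing is configurable).

One generative choice deserves emphasis.  Because the null model estimates
the regional pool from the observed table itself, *multinomial* sampling
from a shared filtered distribution is indistinguishable from the null —
it cannot produce mean ses < 0.  Convergent assembly below the null
expectation requires communities to track their expected composition more
tightly than multinomial noise allows.  The two selection regimes therefore
carry a `selection_strength` parameter (default 0.8): that fraction of each
sample's reads is allocated deterministically to the filtered expectation
(largest-remainder rounding), the rest multinomially.  Ecologically this
models strong deterministic filtering with reduced demographic
stochasticity; statistically it is what makes `homogeneous_selection`
register as ses < 0 while leaving `heterogeneous_selection` ses > 0
(site-level filters differ, so between-site divergence dominates).

What a green test establishes: the statistics recover the regime the
generator realized, at the stated sizes.  What it does not: the generator
has no sequencing error, chimeras, OTU-clustering artifacts, copy-number
variation, temporal dynamics, or multi-dimensional environments (the axis
is scalar by default), and its trait–environment coupling is linear — so
green tests say nothing about robustness to those features of real data.
FRB is generated as a quadrat-level biomass covariate in the metadata (not
a species trait — a CWM over biomass totals is not meaningful).

## Numerical and degenerate-input choices

* Rarefaction is a single seeded draw per sample without replacement
  (multivariate hypergeometric), keeping all-zero OTU columns; one rarefied
  matrix is the convention the package mirrors, and the logged seed makes
  the draw reproducible.  Depth exceeding any sample total is an error
  naming the shortfall samples.
* Null Bray–Curtis moments accumulate in chunks of 100 replicates with
  vectorized pair arithmetic, so 999 nulls on 162 samples stay within
  desk-scale memory; sd uses the n−1 denominator.
* Bray–Curtis on a pair of all-zero samples, zero-variance attributes under
  standardized distance, constant deviation vectors under the t-test,
  singleton PERMANOVA groups, and k ≥ n NMDS all raise informative errors
  rather than propagating NaN.
* Config parsing rejects unknown keys with a nearest-match suggestion;
  parsers report file/line/column.
* All seeds are restored on exit (`with_seed`), so library calls never
  clobber the caller's RNG state; fixed-seed pipeline reruns are
  byte-identical, which the test suite asserts via md5.

## Known limitations

* The pairwise t-test inflation discussed above: dataset-level significance
  of mean ses should be read qualitatively.
* A mild positive bias of mean ses (~0.1–0.15 ses units at 10 samples ×
  2,000 reads in acceptance runs) arises because the regional pool is
  estimated from the data: null draws from the estimated pool are slightly
  less dispersed than observed draws from the true one.  It shrinks with
  total sequencing effort and is far inside the ±0.5 acceptance band.
* MRM standardization and the VPA engine (MRM-based, not
  redundancy-analysis-based) are stated conventions, not the only
  defensible ones; both are recorded in output metadata.
* Phylogenetic null models (βNTI, Raup–Crick) and eigenvector spatial
  predictors are out of scope by design — the approach here is taxonomic
  and uses raw spatial distance.
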