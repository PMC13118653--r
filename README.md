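# rivasm

Community-assembly analysis for microbiomes sampled along cascade-dammed
rivers.

Serial dams partition a river into ordered reaches and potentially
restrict the dispersal of microorganisms between them. Given an OTU
count table, a phylogeny, sample metadata (season, reach, replicate),
dam geometry and environmental measurements, `rivasm` quantifies how
much of the community structure along such a cascade is deterministic
(environmental selection) versus stochastic (dispersal limitation,
homogenizing dispersal, drift), and how that balance shifts between
seasons. It is aimed at microbial ecologists working with 16S-style
amplicon tables from spatially fragmented systems.

## What it computes

- **Diversity**: Shannon, Chao1 and Faith's PD on rarefied counts;
  two-way ANOVA (season × reach) with partial η²; Spearman trends along
  the river; Bray–Curtis on TSS relative abundances; PCoA; PERMANOVA
  (free or season-stratified permutations); multivariate dispersion
  (betadisper, centroid variant).
- **Spatial structure**: dam-count distance matrices (path-additive along
  the cascade), distance–decay regression with Mantel permutation
  inference, Mantel tests against season-standardized environmental
  distances with Benjamini–Hochberg families, and multiple regression on
  distance matrices (MRM).
- **Assembly null models**: abundance-weighted βMNTD and βNTI
  (z-score of phylogenetic turnover against tip-shuffle nulls,
  `(βMNTD_obs − mean_null) / sd_null`), abundance-weighted Raup–Crick on
  Bray–Curtis (RC_Bray), and the standard two-threshold partition —
  βNTI > +2 heterogeneous selection, βNTI < −2 homogeneous selection,
  else RC > +0.95 dispersal limitation, RC < −0.95 homogenizing
  dispersal, |RC| ≤ 0.95 undominated — with per-season process
  fractions.
- **Neutral model**: Sloan's neutral community model,
  `freq(p̄) = 1 − BetaCDF(1/N; Nm·p̄, Nm·(1−p̄))`, fitted by least
  squares; R², Nm, and a Wilson 95% envelope classifying OTUs as
  above/neutral/below.
- **SPEC–OCCU**: specificity–occupancy specialist classification
  (Spec ≥ 0.7 and Occ ≥ 0.7), within-season core-OTU sets (Occ ≥ 0.7),
  and exact set-overlap (Venn) arithmetic with phylum composition
  summaries.
- **Synthetic metacommunities**: a generator with a conserved Brownian
  trait on a simulated phylogeny, a seasonal environmental gradient,
  Gaussian trait–environment selection, dam-permeability mixing
  (ρ per dam crossed), Dirichlet-multinomial drift, and an
  individual-based Moran simulator for the neutral model — so every
  estimator can be validated against data with known generating
  processes.

The null-model loops and the neutral simulator are implemented in C++
(Rcpp); βNTI shuffles tips once and evaluates all pairs, and RC_Bray
seeds each pair from a hash of its sample ids, so results are
deterministic and independent of evaluation order.

## Worked example

Simulate a small two-season survey (400 taxa, 6 reaches, 4 fish per
reach and season) and run the full pipeline:

```r
library(rivasm)

cfg <- sim_config(n_taxa = 400, n_reaches = 6, n_replicates = 4,
                  lib_meanlog = log(2000), lib_sdlog = 0.3,
                  lib_min = 1000, lib_max = 5000, seed = 1)
report <- run_full(run_config(cfg, depth = 1000, n_perm = 199,
                              n_null = 99, seed = 1))

print(report$permanova, digits = 3)
#>                test factor      F    R2     p
#> 1            season season  5.390 0.105 0.005
#> 2      reach_summer  reach  0.966 0.212 0.605
#> 3 dispersion_summer  reach  5.396    NA 0.010
#> 4      reach_winter  reach  9.090 0.716 0.005
#> 5 dispersion_winter  reach 13.413    NA 0.005

print(report$ddr, digits = 3)
#>   season   slope intercept     R2 r_mantel     p
#> 1 summer 0.00547     0.598 0.0139    0.118 0.160
#> 2 winter 0.11662     0.489 0.8837    0.940 0.005

print(subset(report$assembly,
             process %in% c("deterministic", "stochastic")), digits = 3)
#>    season       process fraction
#> 6  summer deterministic   0.0399
#> 7  summer    stochastic   0.9601
#> 13 winter deterministic   0.2391
#> 14 winter    stochastic   0.7609

print(report$ncm, digits = 3)
#>   season      m   Nm    R2 n_otus n_above n_neutral n_below
#> 1 summer 0.0148 31.6 0.766    295      20       257      18
#> 2 winter 0.0244 50.2 0.674    318      20       276      22
```

Reading the output: season separates communities (PERMANOVA F = 5.39,
p = 0.005). Within winter — where the generator plants a steep
environmental gradient, strong phylogenetically conserved selection and
low dam permeability — reaches explain 72% of community variation,
Bray–Curtis dissimilarity climbs 0.117 per intervening dam (Mantel
p = 0.005), and the deterministic share of assembly calls is six times
the summer value. Summer, generated as well-mixed and drift-dominated,
shows no reach separation and an essentially flat distance–decay. Both
seasons fit the neutral occurrence–abundance curve reasonably well
(R² 0.67–0.77); `n_above`/`n_below` count OTUs outside the 95%
envelope. Dispersion tests are significant here, so the winter reach
effect should be read as location plus spread at this toy scale.

`generate_fixture_bundle(cfg, "out/")` writes the same simulated data as
the TSV/Newick files the readers consume, plus a YAML manifest with the
seed and parameters, and `write_report(report, "out/")` saves every
report table as TSV.

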