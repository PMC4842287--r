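# polliflow

Population-genetic analysis of pollen flow in mapped, open-pollinated plant
stands, built around the kind of data a paternity study of a tropical palm
produces: codominant microsatellite genotypes for candidate fathers, seed
trees (mothers) and their open-pollinated offspring, plus planar coordinates
for every adult. The motivating system is a harvested natural stand of
*Astrocaryum aculeatum* (tucumã palm) in the Brazilian Amazon — roughly 124
reproductive adults on 8 ha, 12 seed trees, 10 offspring genotyped per seed
tree, 10 polymorphic microsatellite loci — but every routine is generic.

The package covers, in one coherent toolchain:

* **Genetic diversity** per cohort: allele counts, private alleles, observed
  heterozygosity, Nei's unbiased expected heterozygosity, and the fixation
  index *F* = 1 − H<sub>o</sub>/H<sub>e</sub> with a Monte-Carlo permutation
  test (alleles permuted among individuals within locus, Bonferroni across
  loci) and cohort comparisons (variance F-test, then pooled/Welch t-test).
* **Spatial genetic structure (SGS)**: pairwise Loiselle coancestry
  θ<sub>ij</sub>, a distance-class correlogram with equal pair counts per
  class and 95 % permutation envelopes, the regression slope *b<sub>k</sub>*
  of θ<sub>ij</sub> on ln d<sub>ij</sub>, and the scale-free intensity
  *Sp* = −*b<sub>k</sub>*/(1 − θ<sub>1</sub>).
* **Group coancestry and effective size**:
  Θ = [0.5 n (1 + F<sub>p</sub>) + ΣΣ<sub>i≠j</sub> θ<sub>ij</sub>]/n² and the
  variance effective size N<sub>e</sub> = 0.5/[Θ(n−1)/n + (1+F)/(2n)].
* **Categorical-likelihood paternity**: per-candidate LOD scores, the Δ
  statistic with simulation-derived critical values at a chosen confidence,
  second-parent exclusion probabilities (per locus and combined
  P<sub>2p</sub>), per-mother pollen-immigration rates m<sub>p</sub>, selfing
  counts, and realized pollination distances with the effective pollination
  neighborhood A<sub>ep</sub> = 2πσ<sub>p</sub>².
* **Dispersal-kernel estimation**: maximum-likelihood fit of the
  exponential-power kernel p(r) ∝ exp[−(r/a)<sup>b</sup>] under a spatially
  explicit neighborhood mating model in which each offspring arises by
  selfing (probability *s*), migrant pollen (*m<sub>p</sub>*) or outcrossing
  with a within-plot male weighted by the kernel at his distance.
* **A synthetic-population simulator** reproducing all of the above
  structure — including isolation by distance from short seed dispersal and
  migrant pollen — with full parentage ground truth, used throughout the
  test suite for parameter-recovery and calibration checks.

## Worked example

Simulate a stand with short-distance seed dispersal (three recruitment
rounds with σ = 10 m), then run the full analysis:

```r
library(polliflow)

sim <- simulate_population(sim_config(rng_seed = 42, n_generations_sgs = 3,
                                      seed_dispersal_sigma = 10))
sim$pop
#> <pollen_pop> 244 individuals (112 candidate fathers, 12 mothers, 120 offspring), 10 loci

summarize_diversity(sim$pop, "adult")
#> <diversity_summary> cohort=adult n=124 k=81 A=8.10 Ho=0.681 He=0.708 F=0.039

kin <- loiselle_kinship(sim$pop, "adult")
cg  <- build_correlogram(kin, n_perm = 999, seed = 1)
#> theta_1=0.0396 b_k=-0.0189 (p=0.001) Sp=0.0196

effective_size_report(sim$pop, "adult")
#>     n      F    F_p   Theta   Ne
#> 1 124 0.0385 0.0385 0.00403 61.1

fr  <- allele_frequencies(sim$pop, "adult")
dc  <- delta_criterion(fr, n_sim = 10000, n_candidates = 124, seed = 2)
pat <- assign_paternity(sim$pop, dc$delta_star, freqs = fr)
pat
#> <paternity_result> 120 offspring | assignment rate 88.3% | pollen immigration 11.7% | selfed 0 | distinct sires 56

dispersal_summary(pat, sim$pop)
#> <dispersal_summary> n=106 | mean=38.7 m sd=36.9 m median=28.4 m | Aep=0.85 ha r_ep=52.1 m | KS D=0.675 (p=0)

fit_neighborhood_model(sim$pop, freqs = fr, starts = 5, seed = 3)
#> <kernel_model> s=0.0000 m_p=0.1162 a=9.94 m b=0.691 | mean dispersal 51.3 m | logL=-1439.74
```

Reading the output: the positive first-class coancestry (θ₁ ≈ 0.04) with a
negative slope (b_k < 0, permutation p ≈ 0.001) is the isolation-by-distance
signature the local seed dispersal was meant to induce; Sp ≈ 0.02 is in the
range reported for high-density insect-pollinated trees. The paternity stage
recovers the simulated ~9 % pollen immigration (estimated 11.7 % here —
unassignable offspring include a few true in-plot matings), finds the zero
selfing that was simulated, and the kernel fit puts the selfing rate at the
zero boundary with m_p ≈ 0.12. Individual kernel parameters (a, b) are
weakly identified at this sample size — the likelihood has a ridge along
which the mean dispersal distance is nearly constant — so the fitted mean
dispersal (51 m) is the quantity to interpret.

Real data enter through `read_population("genotypes.csv", "coords.csv")`
(columns `id,cohort,mother_id,<locus>_1,<locus>_2,...` and `id,x,y` in
meters) or `read_genepop()` for genotypes-only files;
`run_pipeline(run_config(...))` drives every stage end-to-end and writes
per-stage TSV tables plus a `metrics.json` bundle.

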