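---
title: "Models and methods behind polliflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polliflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polliflow)
```

polliflow analyzes codominant genotypes from a mapped plant stand with three
cohorts: candidate pollen donors, seed trees ("mothers", themselves also
pollen candidates), and open-pollinated offspring of known mothers. This
vignette states the models actually implemented, the parameters that matter,
the numerical choices, and what the simulation-based tests do and do not
establish.

## Diversity and the fixation index

Per locus we report the number of alleles, observed heterozygosity $H_o$
(fraction heterozygous among individuals typed at the locus) and Nei's
unbiased gene diversity
$$\hat H_e = \frac{2n}{2n-1}\Big(1 - \sum_a \hat p_a^2\Big),$$
with $n$ the individuals typed. The multilocus fixation index is the
ratio-of-sums aggregate $F = 1 - \sum_l H_{o,l} / \sum_l H_{e,l}$, which
weights loci by their diversity instead of averaging per-locus ratios (the
per-locus $F_l$ are also returned). Loci monomorphic across *all* genotyped
individuals are excluded from every index but listed in the output; a locus
monomorphic in one cohort but variable in the other still contributes, since
cohorts are meant to be comparable on a common panel.

Significance of $F$ is assessed by permuting gene copies among individuals
within each locus — which preserves allele counts exactly and breaks only
the within-individual association — and recomputing $F$; the two-sided
p-value uses the $(b+1)/(B+1)$ correction so it can never be zero. Per-locus
p-values are Bonferroni-adjusted across loci. Cohort contrasts of $A$,
$H_o$, $H_e$ and $F$ use per-locus values: an F-test of variance homogeneity
chooses between the pooled-variance and Welch t-test at $\alpha = 0.05$;
both branches are ordinary `stats::var.test()` / `stats::t.test()` calls.

## Pairwise coancestry and spatial genetic structure

Kinship between individuals $i, j$ uses the Loiselle
allele-frequency-covariance estimator. Writing $p_{ila} \in \{0, 0.5, 1\}$
for the frequency of allele $a$ in individual $i$ and $\bar p_{la}$ for its
reference frequency estimated from $n_l$ gene copies,
$$\theta_{ij} = \frac{\sum_l \sum_a \big[(p_{ila}-\bar p_{la})(p_{jla}-\bar p_{la})
 + \bar p_{la}(1-\bar p_{la})/(n_l-1)\big]}{\sum_l \sum_a \bar p_{la}(1-\bar p_{la})}.$$
The multilocus value is a ratio of summed numerators to summed denominators,
and loci missing in either member of a pair are dropped from that pair's
sums; pairs sharing no typed locus are returned as `NA` and flagged.
Reference frequencies default to the analyzed cohort itself, the usual
convention for within-population SGS. A consequence worth knowing: with
self-referenced frequencies the estimator is *relative* — the all-pairs mean
sits near $-1/(n-1)$ plus the sampling correction, so absolute relatedness
common to the whole sample is invisible to it. This is why, in simulations
that accumulate stand-wide drift, the group-coancestry signal appears mostly
through the inbreeding term rather than through $\sum \theta_{ij}$.

The correlogram bins the $n(n-1)/2$ pairs into (by default) ten distance
classes holding equal pair counts, via ranks with ties assigned to the lower
class. The null envelope per class is the 2.5/97.5 percentile of class means
under random permutation of individuals among mapped locations (genotypes
fixed, the distance multiset preserved); the same permutations give the
p-value of $b_k$, the OLS slope of $\theta_{ij}$ on $\ln d_{ij}$ computed
over *all* pairs (not class means), natural log. The intensity statistic is
$Sp = -b_k / (1-\theta_1)$ with $\theta_1$ the first-class mean. Defaults
follow standard practice for this analysis: 10 classes, 10,000 permutations.

## Group coancestry and variance effective size

$$\Theta = \frac{0.5\,n\,(1+F_p) + \sum_{i\neq j}\theta_{ij}}{n^2}, \qquad
N_e = \frac{0.5}{\Theta\frac{n-1}{n} + \frac{1+F}{2n}},$$
where $F_p = \max(F, 0)$: a heterozygote excess does not make individuals
"less than non-inbred" for drift purposes. The formula is derived by
equating the drift variance of allele frequencies in the sampled group with
that of an idealized population of size $N_e$. Whether $F$ should also be
truncated inside the $N_e$ denominator is genuinely ambiguous in the
literature this estimator comes from; polliflow truncates in both places by
default for internal consistency and exposes `truncate_f = FALSE`. Note a
worked-example curiosity: evaluating the closed form at $\Theta = 0.023$,
$n = 124$, $F = 0$ gives $N_e \approx 18.6$, and the unit tests pin that
arithmetic down — a reminder that reported round numbers cannot always be
regenerated from reported inputs.

## Paternity: transition probabilities, LOD, and the Δ criterion

The building block is the single-locus Mendelian transition probability
$P(g_o \mid g_m, g_f)$, computed by enumerating the four equiprobable
gametic combinations; summed over all offspring genotypes it is exactly 1
for every parental pair, and the tests enforce this at a 4-allele locus. A
candidate's LOD is
$$\mathrm{LOD} = \sum_l \ln \frac{P(g_o \mid g_m, g_c)}{P(g_o \mid g_m, \text{random male})},$$
the denominator being the paternal-allele-frequency formulation under
Hardy–Weinberg. With zero genotyping error (the default, appropriate for a
panel validated to have no scoring error) any Mendelian mismatch excludes
the candidate outright; a nonzero `error` instead mixes the transition
probability with the background term. Alleles required of the father but
unseen in the reference sample — which happens when migrant pollen carries
novel alleles — receive a frequency floor of half a gene copy rather than
probability zero, so such offspring are cleanly classified as migrant-sired
instead of crashing the mother-compatibility check; genuine mother–offspring
incompatibility is tested directly on shared alleles and those offspring are
excluded from totals with a warning.

The Δ statistic is the LOD gap between the two most likely non-excluded
candidates (the top LOD itself if only one candidate is compatible). Its
critical value Δ\* comes from simulation: offspring of random Hardy–Weinberg
parents are generated from the candidate-population frequencies; the true
father is present in the candidate set with probability `prop_sampled`
(default 0.60); fresh pools of unrelated candidate males are drawn per block
of 1,000 simulated offspring; and Δ\* is the smallest threshold at which the
fraction of passing offspring whose best candidate is the true father
reaches the requested confidence (default 80 %, 10,000 simulated offspring).
When the loci cannot support the requested confidence, Δ\* is `+Inf` with a
warning — assignment is then impossible rather than silently unreliable.
Assignment ties in LOD are broken by geographic proximity to the mother,
then id, making outputs deterministic. Offspring with no passing candidate
are attributed to migrant pollen, so the immigration rate $m_p$ is the
unassigned fraction; assignment of the mother herself is counted as selfing.
Second-parent exclusion probabilities use the standard codominant-locus
expression (with $a_k = \sum_i p_i^k$)
$Q_2 = 1 - 2a_2 + a_3 + 3a_2a_3 - 3a_5 - 2a_2^2 + 2a_4$, validated against
exhaustive trio enumeration to $10^{-12}$, and combine as
$P_{2p} = 1 - \prod_l (1 - Q_{2l})$.

## Dispersal and the neighborhood mating model

Pollen dispersal uses the two-dimensional exponential-power family
$$p(r; a, b) = \frac{b}{2\pi a^2 \Gamma(2/b)} e^{-(r/a)^b},
\qquad \delta = a\,\frac{\Gamma(3/b)}{\Gamma(2/b)},$$
with scale $a$ in meters and dimensionless shape $b$ ($b = 1$ exponential,
$b = 2$ Gaussian, $b < 1$ fat-tailed). The likelihood of each offspring is
the three-way mixture
$$L_o = s\,T(g_o|g_m,g_m) + m_p\,P_{bg}(g_o|g_m)
 + (1-s-m_p) \sum_j w_j(a,b)\, T(g_o|g_m,g_j),$$
with kernel weights $w_j \propto p(d_{mj}; a, b)$ normalized over the
within-plot males (the mother excluded from her own outcross set — selfing
is its own component; all sampled adults compete, with no distance cutoff).
Weights are normalized over the *sampled* candidates because the plot is
finite; "no neighborhood cutoff" does not mean an infinite plot. Migrant
gametes draw from the within-plot adult allele frequencies — a conservative
choice that makes migrants maximally confusable with residents.
Optimization runs on transformed parameters ($s = \mathrm{logit}^{-1}(u)$,
$m_p = (1-s)\,\mathrm{logit}^{-1}(v)$, $\log a$, $\log b$) with BFGS from
five starts (one neutral, the rest jittered), convergence tolerance
$10^{-10}$ on the relative log-likelihood; standard errors come from the
numerical Hessian by the delta method and are reported as `NA` for fixed or
boundary parameters ($|u| > 8$ flags a boundary, as when $\hat s \to 0$).

Two facts about identifiability, established by the package's own
parameter-recovery runs: $s$ and $m_p$ are recovered tightly (within ±0.05
at 240 offspring and 10 loci), while $(a, b)$ individually are noisy — the
likelihood has a ridge along which the implied mean dispersal distance
$\delta$ is nearly constant, and $\delta$ itself is recovered within a few
meters. Interpret $\delta$, not $a$, at these sample sizes.

The dispersal summary offers two conventions for the "axial variance"
$\sigma_p^2$ that feeds $A_{ep} = 2\pi\sigma_p^2$: `"radial"` (default)
takes $\sigma_p$ as the SD of realized pollination distances — the
convention under which a 49 m SD gives $A_{ep} = 1.51$ ha and an effective
radius of 69 m — and `"axial"` takes the variance of one Cartesian component
under isotropy, $\sum d_i^2 / (2N)$. The mating-versus-distance $R^2$
(binned mating counts regressed on bin-center distance) is reported but
labeled approximate: the construction of that statistic in field studies is
rarely specified precisely enough to reproduce.

## The synthetic-population generator

`sim_config()` defaults encode the stand the package is aimed at: 124
adults on a 400 m × 200 m (8 ha) plot, 12 of them seed trees with 10
offspring each, 10 microsatellite loci with 3–19 alleles, zero selfing
(protogyny), 9 % migrant pollen, and an exponential-power kernel with
$a = 20$ m, $b = 0.9$. Founder allele frequencies are symmetric-Dirichlet
with concentration 0.3: microsatellite panels typically show a few common
and many rare alleles, and this choice reproduces realistic expected
heterozygosity (~0.6–0.7) and combined exclusion power (~0.999) — a flat
Dirichlet (`dirichlet_alpha = 1`) gives implausibly even spectra and
near-perfect exclusion, which would flatter the paternity module. Spatial
genetic structure is induced, when requested, by `n_generations_sgs` rounds
of local recruitment: each round resamples the stand with daughters placed a
Gaussian step (sd `seed_dispersal_sigma`, reflected at plot edges) from
their mothers and sired through the pollen kernel. Three rounds at
$\sigma = 10$ m produce first-class coancestry ≈ 0.04–0.07 and
$b_k \approx -0.02$, the qualitative isolation-by-distance signature of
short seed dispersal. Adults are otherwise uniform on the plot; the true
stand's point pattern (clustered vs uniform) is unknown, and the uniform
default is the simpler assumption.

What the generator does *not* emulate: genotyping error beyond an optional
uniform mistyping rate (default 0), null alleles, linkage, mutation,
overlapping generations with demographic bookkeeping, anisotropic
dispersal, and temporal variation in flowering. Tests passing on these
simulations therefore establish internal correctness and statistical
calibration of the estimators under the stated model — not robustness to
scoring artifacts or demographic complications in real data.

## Numerical and design notes

* Problem sizes in the test suite are chosen to keep the default run at a
  few minutes: null-calibration uses 200 replicates of 40-adult stands with
  199-permutation envelopes; parameter recovery uses one 124-adult,
  240-offspring stand at fixed seed; the structure sign-test uses 20
  replicates of 80-adult stands.
* Pair distances of exactly zero are rejected in the correlogram
  (coincident adults indicate a data error); class ties go to the lower
  class; `b_k` on a constant kinship matrix is exactly 0.
* All stochastic entry points accept a seed, and `simulate_population()` is
  bit-reproducible from `rng_seed`. The pipeline derives per-stage seeds
  from one master seed so full runs are byte-identical.
* Missing genotypes are an explicit `NA` pair (a half-missing pair is
  coerced to fully missing); GenePop `00`/`000` codes map to missing at the
  boundary; allele labels are integers (fragment sizes) and pairs are
  stored sorted, so unordered-pair equality is plain equality.
* GPS field coordinates can be projected to local planar meters with
  `project_latlon()` (equirectangular about the centroid), adequate below
  ~1 km extent.

## Known limitations

* The Loiselle estimator with self-referenced frequencies measures
  *relative* coancestry; group coancestry built from it mostly reflects
  structure, and stand-wide relatedness enters through $F$.
* The Δ-criterion simulation draws parents from Hardy–Weinberg proportions;
  strong SGS among true parents makes the criterion slightly conservative.
* Cryptic gene flow (unsampled migrants compatible by chance) biases
  $\hat m_p$ downward at high exclusion power by at most the compatibility
  probability $1 - P_{2p}$ per migrant; with ten informative loci the bias
  is well under the Monte-Carlo noise.
* The $R^2$ distance-dependence statistic is a descriptive device, not an
  inferential one.
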