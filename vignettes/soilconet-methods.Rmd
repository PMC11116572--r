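---
title: "soilconet: models, design choices and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{soilconet: models, design choices and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilconet)
```

## Scope

`soilconet` implements the downstream analysis of a paired 16S/ITS amplicon
survey of heavy-metal-contaminated agricultural soil: pollution indices,
alpha and beta diversity with group tests, environment-taxon association,
and cross-domain (bacteria-fungus) co-occurrence networks with Zi-Pi
keystone classification. It starts from ASV count tables; read processing
(denoising, chimera removal, taxonomy assignment) is out of scope. Because
the motivating study's raw data and background values are not reproducible
at desk scale, the package ships a community simulator with known ground
truth, and all quantitative guarantees are stated against that synthetic
world.

## Pollution indices

For each metal, the contamination factor is the ratio of measured to
geochemical background concentration, CF = C_measured / C_background, and
the pollution load index of a sample is the geometric mean of its CFs,
PLI = (CF_1 x ... x CF_n)^(1/n), computed in log space. A zero CF forces
PLI = 0 exactly rather than underflowing. Classes follow the conventional
strict-inequality bands (CF: <1 none, 1-3 moderate, 3-6 considerable, >6
highest; PLI > 1 contaminated). Values sitting exactly on a band edge go to
the *lower* class because the definitions are written with strict
inequalities; `boundary = "upper"` flips this, and the choice only matters
on a measure-zero set. Group-level PLI is the arithmetic mean of per-sample
PLIs, matching the "average PLI" convention. All concentrations are mg/kg;
metadata files may declare ng/g and are converted exactly once on read.

## Diversity and group comparison

Per sample we report Good's coverage 1 - F1/N, the bias-corrected Chao1
estimator S_obs + F1(F1-1)/(2(F2+1)), and the Simpson index. Simpson
defaults to the Gini-Simpson form 1 - sum(p_i^2): reported bacterial values
near 1.00 in this literature are only consistent with that form;
`dominance` and `inverse` variants are available. The bias-corrected Chao1
denominator (F2 + 1) avoids division by zero when doubletons are absent;
with F1 <= 1 the estimate collapses to observed richness, which the tests
assert.

Bray-Curtis dissimilarity is computed on relative abundances, where it
equals half the Manhattan distance. Ordination is principal-coordinate
analysis (Gower double-centering, axes by eigenvalue, explained fractions
relative to the positive spectrum). The literature this package follows
often labels a Bray-Curtis ordination "PCA"; since the two are not the
same, both `ordinate()` (PCoA on any distance matrix) and `ordinate_pca()`
(covariance PCA on relative abundances) are provided, and neither is
claimed to be the original study's exact procedure.

ANOSIM uses the rank statistic R = (rB - rW) / (M/2) with M = n(n-1)/2.
Group comparisons of scalar indices use the two-sided Mann-Whitney test,
permutation-exact (all choose(n, n1) splits of the observed, possibly tied,
ranks) when both groups have at most 8 samples, and the tie-corrected
normal approximation otherwise. Permutation p-values throughout use the
positively biased, never-zero estimator (1 + b) / (1 + m) with seeded
permutations; exact enumeration modes (all label assignments, all matrix
permutations) exist for small fixtures and are what the oracle tests
compare against. With equal group sizes the minimal attainable exact ANOSIM
p is 2/choose(n, n/2), because complementary assignments induce the same
partition.

## Association analysis

Spearman's rho is the Pearson correlation of average ranks; p-values use
the t approximation with n - 2 degrees of freedom, with an exact
permutation mode for n <= 8 (at the survey's n = 9 and 7 the approximation
is adequate but not exact, which is documented rather than hidden).
Constant vectors return rho = 0, p = 1 rather than NA so that heatmaps over
sparse taxa stay total. Benjamini-Hochberg adjustment is the step-up
q_(i) = min_{j>=i} m p_(j)/j capped at 1. One BH *family* is one analysis
surface: one environment-taxon heatmap, one genus-level cross-domain
matrix, or all pairs tested during one network build. A caution learned in
testing: BH is not idempotent (re-adjusting q-values inflates them
wherever the step-up minimum binds), so q-values are computed once per
family, never iterated.

The genus-level cross-domain screen keeps genera whose mean relative
abundance within their domain exceeds 10% by default; "mean across
samples" is our reading of the underlying convention, with a per-sample
maximum mode as an alternative. The Mantel test correlates
(Spearman) the lower triangles of two distance matrices and permutes one
matrix's rows and columns jointly.

All association statistics are computed on raw relative abundances with no
compositional correction (no CLR, no SparCC-type adjustment). That is a
deliberate fidelity choice - the workflow being reproduced uses plain
Spearman - and its consequences are discussed under *Limitations*.

## Co-occurrence networks

Taxa present in at least a third of samples (configurable) are tested
all-against-all, within and across domains, with Spearman on relative
abundances; BH runs over all tested pairs of that build; an edge requires
|rho| > 0.7 *and* q < 0.05; isolated nodes are dropped. The prevalence
filter is the largest fidelity gap: the source workflow states no filter,
yet its node counts are far below its ASV counts, so some filter clearly
existed; ours is explicit and configurable.

Module detection is greedy modularity maximization (igraph's fast-greedy)
on the unweighted, sign-blind graph - negative edges are a percent or two
of these networks, and treating the qualified edge set as unweighted
matches common practice in this literature. Because the greedy merge path
can tie at equal modularity (a single clique ties Q = 0 at every cut), the
implementation deterministically picks the coarsest partition among cuts
within 1e-12 of the maximal Q.

Within-module connectivity is Zi = (k_is - mean_s)/sd_s over the node's
module s (0 when the sd vanishes), and among-module connectivity is
Pi = 1 - sum_t (k_it/k_i)^2; both computed on the unsigned qualified-edge
graph. Roles use the standard thresholds: network hub (Zi > 2.5 and
Pi > 0.62), module hub (Zi > 2.5), connector (Pi > 0.62), else peripheral;
the keystone set is the union of the non-peripheral roles.

## The synthetic world

The generator emulates the survey design: two groups (9 contaminated, 7
uncontaminated samples), seven metals (Mo, Cd, Sb, Cu, Zn, Hg, Pb), ten
physicochemical variables, paired bacterial (150 ASVs) and fungal (50 ASVs)
tables at depth 50,000 reads per domain.

**Metals.** Concentrations are log-normal around group means specified as
CF x background, mean-parameterized so that a zero CV reproduces the group
mean exactly. The contaminated-group CF means are the published factors
(Cd 30.35, Hg 11.26, Pb 5.46, Zn 5.19, Cu 2.46) with Mo and Sb sub-unity;
Sb is trace-level in both groups (CF 0.0125 and 0.0033, mirroring reported
ng/g-scale concentrations). Background values are unpublished in the
source; we fix plausible NW-China loess agricultural soil backgrounds once
(Mo 1.2, Cd 0.2, Sb 1.0, Cu 24, Zn 69, Hg 0.02, Pb 19 mg/kg). A shared
per-sample lognormal factor (weight 0.6) makes metals mutually
rank-correlated within a group, as co-contamination from a common source
produces. Contaminated-group CV is 0.5 (field volatility), uncontaminated
0.2. Physicochemical variables are truncated normal draws at the published
group means and SDs (e.g. MBC lower in the contaminated group).

**Counts.** A Gaussian copula over log-abundances drives co-occurrence:
per-module factors f_m with inter-factor correlation rhoF =
rho_between/rho_within; module members load sqrt(rho_within); hubs load
sqrt(min(rho_within + boost, 0.98)); residuals restore unit variance.
Latent deviates scale into log-abundance by `latent_sd` (1.5), add a
baseline, pass through a softmax within each domain, and counts are drawn
multinomially at fixed depth - so compositionality and zeros arise
exactly as sequencing produces them (explicit zero-inflation exists but is
off by default). Metal responders add `effect_size_metal` times the
standardized log concentration of their assigned metal to their latent
log-abundance.

Two structural choices came out of pre-build simulation and are worth
stating plainly:

* *Structural taxa are moderately abundant; the background carries the
  mass.* Planted taxa draw baseline log-abundance N(0, 0.5) while
  background taxa draw N(2, 1.5). A taxon sampled at a handful of reads
  cannot carry planted rank correlation at any depth, and softmax closure
  attenuates cross-taxon correlation in proportion to the planted taxa's
  share of community mass; a mass-dominant background keeps that
  attenuation small.

* *Group-dependent interaction strength.* `rho_group_scale` multiplies
  planted correlations per group (default: 1 contaminated, 0.85
  uncontaminated), encoding the survey's central qualitative finding -
  denser co-occurrence under long-term moderate contamination - so that
  per-group networks built from the default world reproduce that
  direction. A side effect worth knowing: scaling the latent variance
  shifts group-mean relative abundances (a Jensen effect), so under the
  default world *every* structural taxon carries some group signal; the
  responder-power experiment therefore sets both scales to 1.

**The connector ceiling.** A latent variable correlated r with members of
m mutually uncorrelated modules (member loading sqrt(rho_w)) requires
m r^2 / rho_w <= 1, i.e. r <= sqrt(rho_w/m) - about 0.55 for rho_w = 0.9
and m = 3. This is a positive-semidefiniteness fact, not a simulator
artifact: "connectors correlated at rho_within with three orthogonal
modules" cannot exist. Connectors therefore load on their spanned factors
at the maximum the covariance budget admits,
r = sqrt(rho_w (1 + (m-1) rhoF) / m), which grows with the between-module
correlation; at rho_between = 0.4-0.5 the ceiling reaches ~0.73-0.79.
After rank and compositional attenuation the realized sample correlation
sits near 0.65-0.70 - *below* the 0.7 edge threshold. Consequently the
planted-structure recovery experiment uses two probes on the same data:
module recovery (adjusted Rand index) and hub Zi on the default r = 0.7
network, where modules are near-saturated and the hub is reliably its
module's best-connected node; and connector Pi on an r = 0.5 build, the
only regime where connector edges into all three modules survive. Hub
"top-decile Zi" is judged within the hub's own module: Zi is a
within-module z-score, and at r = 0.7 cross-module Zi comparisons are pure
noise between saturated cliques.

**Defaults calibrated by simulation.** The default metal effect size is 3
(latent log-abundance SD units per SD of log metal), set by the
power-simulation this design prescribes: it is the smallest round value
at which the planted responders are recovered in the environment-taxon
heatmap with power ~0.9 at n = 16 under BH; at effect 2 power is ~0.6.
Module structure defaults to eight 12-taxon modules at rho_within = 0.95:
at n = 9 with ~20,000 BH-corrected pairs, only observed |rho| above ~0.9
survives, so a world with few or weaker modules produces empty networks -
the published edge counts imply real soil data is saturated with such
near-monotone pairs.

## What a green test does and does not establish

The acceptance suite establishes: exactness of every index against
brute-force oracles (1e-10 on hundreds of random fixtures); exact
reproduction of the classification thresholds on boundary-straddling
grids; FDR control of the network builder on truly null communities;
recovery of planted modules, hubs and connectors at the probe thresholds
above; the contaminated-vs-uncontaminated density direction with a >= 95%
positive-edge fraction in the denser network; exact agreement of ANOSIM
and Mantel with exhaustive enumeration plus null-uniform p-values; and
responder detection power >= 0.8 with falsely flagged null taxa at or below
the nominal 5%.

It does not establish: behaviour on real amplicon data with its
zero-inflation, phylogenetic correlation, taxonomic misassignment and
library-size variation (the generator models none of these); the original
study's numeric results (unreproducible without its deposited reads and
unpublished backgrounds); or false-discovery control *among discoveries*
in the presence of strong responders - strong planted effects make a few
background taxa genuinely anti-correlated with metals through
compositional closure (about one taxon per simulated study at default
settings), and raw Spearman cannot tell such spillover from biology. That
last point is a known limitation of the replicated method itself, not of
the implementation, and is the reason the false-positive criterion is
stated as a rate over null taxa.

## Numerical conventions

Permutation p-values are (1 + b)/(1 + m) (sampled) or the enumeration
fraction including the identity (exact). Tie handling is average ranks
everywhere. Class-boundary ties go to the lower class. Degenerate inputs
are total: constant vectors give rho = 0 / p = 1, empty graphs give
singleton modules and zeroed topology with a warning, zero CFs give
PLI = 0, samples with zero reads are rejected. All randomness (generator,
permutation tests, module detection) is seeded, and the pipeline writes
its seed and thresholds into a JSON manifest with per-file checksums; the
end-to-end run is bit-reproducible for a fixed seed.
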