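---
title: "Models and methods behind shelltraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shelltraits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelltraits)
```

`shelltraits` compares eggshell surface traits — areal surface roughness
(S~a~, nm), wettability (water contact angle, degrees) and
calcium-carbonate content (% of dry shell mass) — between obligate
brood-parasitic birds and non-parasitic species, while accounting for the
fact that species are not statistically independent: close relatives
resemble each other because of shared ancestry. This vignette explains the
models, the choices behind the defaults, and what the package's validation
on synthetic data does and does not establish.

## Trait derivations

**Surface roughness.** A profilometer scan is a grid of surface heights.
Eggshell fragments are curved, so `compute_sa()` first fits a full
second-order polynomial reference surface
$z \approx a x^2 + b x y + c y^2 + d x + e y + f$
by ordinary least squares over all pixels (pixel indices, centered for
conditioning, serve as coordinates) and then returns the arithmetic mean
absolute deviation of the heights from that surface — the standard areal
S~a~ parameter computed against a curved reference plane. Two properties
pin the implementation down and are tested: S~a~ is invariant to adding any
quadratic surface to the grid, and for an i.i.d. Gaussian height field of
standard deviation $s$ the expected value is $s\sqrt{2/\pi}$ (the mean
absolute value of a centered normal), which a 768 × 576 synthetic scan
reproduces within 1%. Eggs are scanned at several locations;
`egg_mean_sa()` averages the per-scan values, and all downstream analyses
work on per-egg means.

**Wettability.** The drop-shape analyzer records the left and right
contact angle of a sessile droplet once per second; spreading is
negligible after five seconds, so `ca_at_settle()` takes the mean of the
left and right readings at the 5 s mark. `classify_wettability()` maps CA
to categories with upward-classifying boundaries: hydrophilic below 90°,
hydrophobic from 90° up to (not including) 150°, superhydrophobic from
150°. Note one caveat for users reading the source literature in this
area: reported prose sometimes labels sub-90° shells "hydrophobic"; the
package implements the inequalities as written above and leaves
interpretation to the analyst.

**Calcium carbonate.** `caco3_percent()` converts an ashing series
(empty crucible, crucible + dried fragment, crucible + ash) to ash mass as
a percentage of dry fragment mass. Masses are carried at full precision in
grams; the function enforces the physical ordering of the three masses.

## The phylogenetic mixed model

For an egg-level trait $y$ the model is

$$y = X\beta + Zu + \varepsilon,\qquad
u \sim N(0, \sigma^2_p A),\qquad
\varepsilon \sim N(0, \sigma^2_e I),$$

with $Z$ the egg-to-species incidence matrix and $A$ the Brownian-motion
covariance of the phylogeny: $A_{ij}$ is proportional to the shared
root-to-ancestor branch length of species $i$ and $j$. The package
standardizes $A = C/\max(\operatorname{diag} C)$ (so
$\operatorname{diag}A \equiv 1$ on an ultrametric tree): this keeps
$\sigma^2_p$ in squared trait units and makes the **phylogenetic
heritability**

$$H^2 = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2_e} \in [0, 1]$$

scale-free. $H^2 = 0$ means no phylogenetic signal; $H^2 = 1$ means the
between-species variation is fully consistent with Brownian-motion
evolution (the interpretation matches Pagel's λ in phylogenetic GLS).
Setting `A = NULL` in `fit_pmm()` collapses the model to an ordinary
species random intercept, which is how the CA-on-S~a~ mixed model is fit.

**Estimation.** The variance ratio $\theta = \sigma^2_p/\sigma^2_e$ is
profiled: after one symmetric eigendecomposition of $ZAZ'$ the GLS fixed
effects and the profiled $\hat\sigma^2_e$ are closed-form at any
$\theta$, so the one-dimensional profile likelihood is maximized by a
61-point log-spaced grid over $[10^{-6}, 10^6]$ followed by Brent
refinement in the bracketing interval (tolerance $10^{-8}$ on the log
scale), with $\theta = 0$ always evaluated as an explicit boundary
candidate. There is no random initialization, so fits are bit-for-bit
reproducible. The wide $\theta$ range matters because empirical traits
span nearly the whole $H^2$ range (roughness near 0.95, contact angle
near 0). The REML criterion includes
$\log\lvert X'V^{-1}X\rvert$; on balanced one-way layouts with identity
$A$ the REML components reduce to the textbook ANOVA estimators, which
the suite checks to $10^{-6}$, and identity-covariance fits agree with
`lme4::lmer` to the same precision.

**Inference for fixed effects.** Predictor p-values come from a
likelihood-ratio χ² test between nested models fitted by **ML** (REML
likelihoods are not comparable across fixed-effect structures); the
statistic is clamped at zero and referred to the χ² upper tail with df
equal to the number of added coefficients. Fixed-effect t ratios are
reported without a denominator-df correction — they are descriptive, and
the LRT carries the testing burden. Satterthwaite-type df are deliberately
out of scope.

**Identifiability.** With identity $A$ and one egg per species the two
variance components cannot be separated; `fit_pmm()` refuses such designs
rather than returning an arbitrary split. A phylogenetic $A$ makes
single-egg species usable because relatedness links species-level effects.

**Model structure choice.** A single species-level random effect carries
both phylogenetic and any non-phylogenetic species variance; a model with
separate phylogenetic and i.i.d. species effects would not be reliably
identifiable at ~45 species and is not attempted. $H^2$ is therefore an
egg-level quantity: the proportion of total egg-level variance (around the
fixed effects) attributable to the species effect. Both conventions —
standardizing $A$, and omitting a third variance component — shift $H^2$
slightly relative to other software; they are fixed package conventions,
stated here so results are interpreted against them.

## Host matching

The question "do parasite eggs resemble their host's eggs more than
chance?" is answered on pairs. For each parasitic egg with data,
`build_pairs()` emits

* a **host pair**: the parasite egg against its host reference —
  a uniformly sampled egg of the host species (default), or the host
  species mean (`host_rule = "species_mean"`); a parasite with several
  candidate host species and unknown per-egg host identity (the common
  cuckoo situation) always uses the mean of the candidate host species'
  means;
* a **random pair**: the parasite egg against an egg sampled uniformly
  from the non-parasitic eggs, by default excluding that parasite's own
  host species (set `exclude_hosts = FALSE` to include them — the contrast
  then dilutes, which is the point of the switch).

The pair value is the absolute difference of per-egg means.
`compare_pair_types()` reports the random-minus-host difference in group
means with its OLS standard error, t and df = n − 2, and alongside it a
**label-shuffling permutation p**: pair-type labels are permuted across
pairs $B$ times (default 10 000, seeded) and the two-sided exceedance
probability is computed with the $+1/(B+1)$ correction. On a six-pair toy
the Monte-Carlo p matches exhaustive enumeration of all 20 label
assignments.

**A known limitation, found and quantified on synthetic data.** The
label-shuffling null assumes the pair differences are exchangeable. When a
parasitic species contributes several eggs, all of its pairs share the
same species effect and the same host species, so the differences are
clustered; with strong phylogenetic signal ($H^2 \approx 0.9$) and four
eggs per species, the test rejects a true null at roughly 11% instead of
5%, even though the group-difference estimate itself is unbiased (checked
over 4 000 null replicates). With one egg per species, or weak signal, the
size is nominal (~3–5%). Users should treat marginal host-match p-values
from designs with heavy within-species replication with caution; the
package reports the parametric t alongside, which shares the same
limitation (pooled OLS also assumes independent pairs). A hierarchical or
block-permutation scheme would address this but is a different test from
the one implemented here.

## The synthetic-data generator

The generator exists so every stage can be validated against known ground
truth without any external data.

* `simulate_tree()` is a forward pure-birth (Yule) simulation: each of
  $k$ live lineages splits at total rate $k\lambda$; growth stops at the
  requested tip count, tips are extended by a final exponential waiting
  time, and the tree is rescaled to unit height. Lineage-through-time
  means match $2e^{\lambda t}$ over replicates. Yule trees (no extinction)
  keep the generator minimal — tree shape is not the object of study.
* `simulate_traits()` draws species effects
  $u \sim N(0, \sigma^2_p A)$ via Cholesky, adds the parasitism shift
  `beta_parasitism` to the chosen parasitic species, then pulls each
  parasite toward its assigned host by the convex weight
  $w$: $s_p \leftarrow (1-w)s_p + w\,s_{host}$ (so $w = 1$ makes parasite
  and host species values identical and $w$ applied after the shift
  attenuates it — the convergence weight dominates by construction). Egg
  values add i.i.d. $N(0, \sigma^2_e)$ noise. Hosts are assigned uniformly
  among non-parasites or to the nearest non-parasitic relative.
* `simulate_heightmap()` superimposes an i.i.d. Gaussian roughness field
  on a quadratic surface.

The default scenario mirrors the scale of the motivating kind of study:
45 species, 14 parasitic, 2–10 eggs per species, trait on the nanometre
roughness scale (baseline 2 000 nm, species SD 600 nm, egg SD 200 nm,
hence true $H^2 = 0.9$ — roughness-like traits show signal near this
level). The convergence weight has no empirical calibration, so validation
sweeps it rather than fixing a "realistic" value. What the generator does
**not** emulate: measurement-instrument error structure beyond Gaussian
noise, unequal per-trait missingness patterns, pigment or region effects
on museum fragments, and non-Brownian evolution (e.g. Ornstein–Uhlenbeck
attraction); passing tests therefore establish correctness of the
estimators under the stated model, not robustness to violations of it.

Validation sizes were chosen to probe the statistics at the study's own
scale while staying desk-sized: 200 replicate datasets per heritability
level for recovery (mean $\hat H^2$ within ±0.1 of truth at 0.05, 0.5,
0.95 and monotone across levels), 500 null replicates for test size, 200
paired replicates for the $w = 0.8$ vs $w = 0$ power contrast.

## Pipeline conventions and numerical details

* Species present in the egg table but absent from the tree are dropped
  with a logged census (fatal under `strict = TRUE`). Missing trait values
  are dropped per analysis, never imputed, so per-trait sample sizes may
  differ — as they do in real collections.
* Trees without branch lengths are rejected unless the caller explicitly
  requests Grafen heights (node height = (descendant leaves − 1)/(n − 1)),
  because silently defaulting branch lengths would silently change $H^2$.
  Polytomies are retained; the covariance is well defined on them and
  random resolution would smuggle in RNG dependence.
* Taking a taxa subset in `phylo_covariance()` subsets the full-tree
  covariance, preserving root-to-tip depths, rather than pruning and
  re-rooting at the subset's ancestor.
* All randomness (random partners, permutations, generators) descends from
  one integer seed, split deterministically per stage; reports rerun
  byte-identically. Correlation confidence intervals use the Fisher z
  transform. Eigenvalues of $ZAZ'$ are clipped at zero below
  $-10^{-8}\lambda_{\max}$ tolerance (a genuinely indefinite matrix is an
  error); the θ optimum is flagged `boundary` when it lands at 0 or at
  either search bound.
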