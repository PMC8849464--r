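---
title: "Models and methods in landgenr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in landgenr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the synthetic-data tests do and do
not establish about real data.

## The study design the package targets

The archetype is a landscape-genetic survey of an insect disease vector:
a few dozen collection sites across a valley system, roughly ten diploid
individuals per site, each genotyped at a few thousand biallelic SNPs from a
reduced-representation protocol; some sites sampled in two habitat classes
("ecotopes" — domestic structures vs wild nests); and co-registered rasters
of elevation, land cover and roads on a ~250 m grid. Three questions follow:
how diverse and differentiated are the sites, which loci track the domestic
habitat, and which landscape features best explain the spatial pattern of
differentiation.

## Population-genetic estimators

Per-locus gene diversity uses Nei's unbiased estimator
$\hat H_E = \frac{2n}{2n-1}\,2\hat p(1-\hat p)$, and $F_{IS} = 1 - \bar
H_O/\bar H_E$ from multilocus means (0 when $\bar H_E = 0$). Rarefied
allelic richness is the exact hypergeometric expectation
$A_r = \sum_i \left[1 - \binom{N-N_i}{g}\big/\binom{N}{g}\right]$ at a
common rarefaction size $g$ of gene copies; the default $g$ is the smallest
per-locus gene-copy count over the compared groups, so every locus can be
rarefied without extrapolation.

Pairwise differentiation is computed from Nei–Chesser corrected
heterozygosities ($\hat H_S$ with the harmonic-mean sample size and observed
heterozygosity correction; $\hat H_T = h_T + \hat H_S/2\tilde n k$):
Nei $F_{ST} = (\hat H_T - \hat H_S)/\hat H_T$; Hedrick/Meirmans
$G''_{ST} = k(\hat H_T - \hat H_S)\big/[(k\hat H_T - \hat H_S)(1-\hat H_S)]$;
and the standardised $F'_{ST} = F_{ST}/F_{ST(\max)}$ where $F_{ST(\max)}$
treats each group's alleles as private (computable in closed form from the
group frequencies, no literal recoding needed). Multilocus values are ratios
of loci-averaged components. **Truncation at zero:** the unbiased
corrections make these estimators deterministically negative on groups with
identical sample frequencies; because the package consumes them as distance
matrices, negative estimates are truncated to 0. Permutation tests (999
reshuffles of individuals between the two groups, $p=(b+1)/(B+1)$) and
Benjamini–Hochberg adjustment across pairs quantify significance.

Hierarchical F-statistics come from the unbalanced fully-nested
random-effects ANOVA on allele indicators with levels site >
stratum-within-site > individual > gamete. Rather than approximating the
coefficient matrix, the expected sums of squares are computed exactly from
the group sizes ($E[\sum_g n_g\bar y_g^2]$ expansions) and the triangular
system is solved per locus; components are summed over loci before taking
ratios. The two-level collapse of this machinery reproduces Weir–Cockerham's
multilocus $\theta$ exactly, which the tests verify against an independently
coded textbook implementation. Because the field's "four-level" hierarchy
leaves the nesting of collection year versus ecotope ambiguous, both
two-factor sub-models (ecotope-within-site, year-within-site) are available
and reported separately. Significance permutes units at the level
immediately below the tested one: whole individuals among sites, and
stratum labels among individuals within each site.

## The outlier-scan suite

All three scans contrast domestic and wild samples while controlling for
spatial structure through the first three principal coordinates of the
inter-sample geographic distance matrix.

*Random forest.* Genotypes (centred, mean-imputed, and by default
residualised on the spatial axes — the conditioning is a config switch
`residualise | covariates | off`, since published descriptions of
"spatial-structure-corrected" forests do not pin down the mechanism) are
used to classify ecotope with balanced-class subsampling per tree.
Importance is scaled permutation importance (mean decrease in accuracy /
SD); three independent forests are averaged and their pairwise Pearson
correlations serve as a convergence check, with a warning below mean r of
0.5. Loci above importance 3 enter backwards purging: refit, record
out-of-bag error, drop the least important locus, down to two; the subset
minimising OOB-ER (ties to the smaller subset) is the RF flag set. The
default of 5,000 trees keeps desk runs tractable; production analyses
should raise it towards 100,000.

*Partial RDA.* With the binary ecotope there is a single constrained axis;
after residualising genotypes and indicator on the spatial axes, the axis
loadings are proportional to per-locus covariances with the residualised
indicator. Loadings are z-scored and flagged at ±2 SD (permissive, expected
two-sided normal tail 4.6%) and ±3 SD (conservative). The model is tested by
999 permutations of the residualised indicator using the pseudo-F. The
implementation is plain linear algebra and is cross-checked in the tests
against an independent constrained-ordination package on the same data.

*FST–heterozygosity.* Per-locus Wright $F_{ST}$ (size-weighted frequency
variance over $\bar p\bar q$, no finite-sample correction) against expected
heterozygosity. The parametric variant trims the lowest 6% and highest 35%
of loci by $F_{ST}$ and fits a scaled chi-square to the core by truncated
maximum likelihood. A free two-parameter fit on a doubly truncated window is
ridge-degenerate (df can fall while the mean rises with almost no likelihood
cost), so the mean is profiled out by a moment constraint — for each df, the
mean is chosen so the truncated expectation matches the trimmed sample
mean — and only df is searched (Brent on (1, 200)). Right-tail p-values are
assigned to loci with $H_E \ge 0.1$ (the gate below which the chi-square
approximation is unreliable), BH q-values computed, and flags set at
q < 0.05. The non-parametric variant bins loci into 10 equal-count
heterozygosity bins, takes per-bin $\alpha/2$ and $1-\alpha/2$ quantiles,
smooths with a 3-bin moving average (the smoothing scheme is unspecified in
the literature; this choice is fixed and documented), and flags loci outside
the interpolated envelope. A consensus report intersects the four flag sets.

With only two contrast groups the chi-square null has ~1 degree of freedom,
so the parametric scan is conservative and needs on the order of a hundred
samples per ecotope for power at a logit shift of 2 — matching its
reputation for very short outlier lists.

## The MLPE model

For pairwise data $Y_{ij} = \alpha + \beta(X_{ij}-\bar x) + H_i + \tau_{ij}
+ e_{ij}$, the population effect $\tau$ is realised through the covariance
$\Sigma = \sigma^2_e I + \sigma^2_u ZZ^\top$ with $Z$ the pair–population
incidence matrix, giving correlation $\rho = \sigma^2_u/(2\sigma^2_u +
\sigma^2_e) \in [0, 0.5)$ between pairs sharing a population. The variance
ratio $\phi = \sigma^2_u/\sigma^2_e$ is profiled by a one-dimensional
likelihood search on $\log\phi \in [\log 10^{-8}, \log 10^3]$; each
evaluation uses the Woodbury identity through the spectral decomposition of
$Z^\top Z$, so the cost is linear in pairs. ML is the default (fits must be
comparable across fixed-effect structures for AICc); REML is available.
Predictors are centred internally for numerical stability, with intercept
and covariance mapped back, so slopes are exactly invariant to predictor
shifts. The printed equation contains an ecotope main effect while the
interesting contrast is a slope difference; both the main-effect and
interaction models are fitted, and `slope_contrast()` (Wald plus
likelihood-ratio) requires the interaction model. The stratified workflow
builds separate domestic and wild site-distance matrices (a dual-ecotope
site contributes to both, through its respective samples) and fits one
joint two-stratum MLPE — the joint model is primary; separate per-stratum
fits remain available through the same `mlpe()` interface.

## Resistance surfaces and optimisation

Surfaces are rescaled to [1, 100]; continuous surfaces pass through a
monomolecular curve $g(x') = (1-e^{-x'/s})/(1-e^{-1/s})$, with increasing/
decreasing, forward/reversed-input and convex-inverse variants (8 in all,
a documented superset of the commonly used transformation menu, since the
admissible subset is rarely printed), scaled to $R = 1+(m-1)g$. Categorical
surfaces are reclassified with the least-resistance anchor class fixed at 1
to remove scale unidentifiability. Composite surfaces sum component
resistances cell-wise and re-anchor the minimum at 1 (the combination rule
is not standardised in the literature; this one keeps the [1, ·] convention).

Cells become graph nodes with 8-neighbour connectivity; edge resistance is
the mean of the two cell resistances, ×√2 on diagonals. Commute time is
$C(i,j) = \mathrm{vol}(G) R_{\mathrm{eff}}(i,j)$ with
$R_{\mathrm{eff}}$ from the reduced (grounded) Laplacian solved by sparse
Cholesky; a cached evaluator fixes the symbolic factorisation so the
genetic-algorithm loop only updates conductances. Note that commute time is
invariant to a uniform rescaling of all resistances (the random walk is
unchanged: volume and effective resistance scale oppositely); effective
resistance scales linearly. Since the MLPE predictor is standardised, model
ranking is unaffected either way. Current maps solve each focal pair's
potential field; non-focal cells accumulate half the sum of absolute
incident edge currents (through-flow) and focal cells the injected unit.

The GA is real-coded: population 20 × number of parameters, tournament
selection (size 2), BLX-0.5 blend crossover (rate 0.8), Gaussian mutation
(rate 0.2, SD 15% of each gene's range), one elite, stopping after 10
stall generations (defaults; all overridable). Genes are the transform
variant (rounded), log shape, log(m−1), or per-class log resistances. The
objective is the MLPE log-likelihood of the genetic distances on the
standardised commute distances. Model selection uses
$AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ = surface parameters + 1
(continuous surface 3, categorical surface one per class; distance-only
model k = 2, null k = 1 — the accounting that reproduces published model
tables) and $n$ = number of sites by default; the literature is divided on
sites vs pairs, so `n_aicc` is exposed. Bootstrap ranking resamples 85% of
sites without replacement, refits each model's MLPE on the cached effective
distances (surface parameters frozen — re-optimising inside thousands of
iterations is neither feasible nor part of the published procedure), and
reports average AICc, average rank and top-model percentage.

## The synthetic generator

The generator emulates the target study design: 25 sites (7 dual-ecotope)
of 10 diploids, 2,500 SNPs, a 100×100 grid of 250 m cells, elevation
autocorrelation length 5 km, missingness 2% MCAR — these defaults are the
study conditions, not tuning knobs. Elevation is a unit-variance Gaussian
random field with exponential covariance, synthesised by circulant
embedding (FFT, negative embedding eigenvalues clipped — none arise at the
default sizes) and mapped to 1500 + 500z m, clipped to [0, 3000]. The
true resistance surface is a monomolecular transform of elevation (variant
1, shape 0.3, maximum 100 by default — a strong, saturating
elevation barrier). Site allele frequencies follow a Gaussian copula:
per locus $p_0 \sim \mathrm{Beta}(2,2)$, latent site vector
$z \sim N(0, \exp(-d_{\mathrm{eff}}/\lambda))$ mapped through the normal
CDF to quantiles of $\mathrm{Beta}(p_0(1-F)/F, (1-p_0)(1-F)/F)$. This keeps
the F-model marginals that FST-outlier theory assumes (multilocus
Weir–Cockerham $\theta \approx F$, verified against a brute-force
simulator) while giving spatial correlation that decays with *effective*
distance at scale $\lambda$ (default: the median pairwise effective
distance, a scale-free choice that yields a clear but noisy
isolation-by-resistance signal — empirical Mantel r of roughly 0.5–0.7 at
desk sizes). Outlier loci (default 5; the effect size of domestic
adaptation is unknown, so the logit shift δ = 2 is a simulation knob, not
an estimate) shift every domestic group's frequency on the logit scale,
which respects [0, 1]. Genotypes are Binomial(2, p) per diploid.
Positive-definiteness of the site correlation is enforced with a 1e-8
diagonal jitter. One global seed expands into per-stage substreams through
a documented Lehmer-step rule, so each stage is independently reproducible.

What the generator does **not** emulate: linkage between loci, genotyping
error and allele dropout, non-equilibrium demography (bottlenecks,
expansions), isolation by environment beyond the single resistance truth,
and non-random missingness. Passing tests therefore demonstrate estimator
correctness and recovery under the stated model, not robustness to those
real-data complications.

## Problem sizes used by the tests

The test-suite simulations are sized for a desk machine and are stated here
as the package's own choices: null calibration of the scans at 25 demes ×
1,000 loci × 20 replicates; scan power/precision at 20 sites × 10 diploids
× 200 loci × 20 replicates with 1,000-tree forests; MLPE coverage over 200
simulated pair sets of 25 populations; slope-contrast calibration with
noise set analytically so the per-stratum distance–differentiation
correlation is ≈ 0.4; landscape-model recovery on 60×60 rasters, 15 sites,
500 loci, GA capped at 20 generations, 20 replicates; and an end-to-end
pipeline run at 12 sites × 300 loci. The acceptance script uses 20 sites ×
10 diploids × 1,000 loci with 2,000-tree forests and a 20-generation GA.

## Numerical conventions and degenerate inputs

Permutation p-values always use $(b+1)/(B+1)$, so no p is exactly zero.
Monomorphic loci: $H_E = 0$, $F_{IS} = 0$ by convention, $A_r = 1$; LD r²
is undefined for monomorphic pairs, which are excluded and counted.
Constant rasters cannot be rescaled (error); constant distance matrices
make Mantel/Pearson correlation undefined (reported as such). Pairs with
$H_T = 0$ get differentiation 0 and a flag. GA ties and RF purging ties
resolve toward smaller subsets; all stochastic steps take explicit seeds.
Missing genotypes are handled pairwise-complete in the summary statistics
and mean-imputed only inside the multivariate scans (the matrix methods
need complete data; at the 2% MCAR default this is benign).
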