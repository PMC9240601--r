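---
title: "Methods: quantifying and mapping heterophylly"
author: "heteroGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and mapping heterophylly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the numerical choices, and the
boundaries of what the package's tests demonstrate. It is the design
record: wherever a method admitted more than one reasonable reading, the
choice made here is stated with its rationale.

## The phenotype: four leaf classes on one tree

Heterophyllous trees carry a bottom-to-top series of leaf morphologies.
We work with four classes keyed by the leaf index LI = LL/LW (leaf
length over leaf width): linear (LI ≥ 4), lanceolate (4 > LI ≥ 2),
ovoid (2 > LI ≥ 1) and broad-ovate (LI < 1). The classifier applies
these half-open intervals with an absolute boundary tolerance of 1e-9,
which absorbs floating-point noise in *measured* ratios without
changing the partition at any physically meaningful resolution.

### From image to outline

Segmentation assumes a red backdrop: a pixel is background iff
R − max(G, B) > 40 on the 8-bit scale. The threshold separates a
saturated red sheet from green/brown leaf tissue with a wide margin; it
is a parameter (`redMargin`) for other lighting setups. The largest
connected foreground component is kept and holes are filled (EBImage).

Tracing extracts the 0.5 level set of the binary mask with linear
interpolation (`grDevices::contourLines`) and then applies 10
iterations of Taubin lambda/mu smoothing (lambda = 0.5, mu = -0.53).
Marching-squares contours of binary masks carry a pixel-quantization
staircase that inflates perimeter estimates by ~6%; Taubin smoothing is
a low-pass filter constructed to remove that oscillation *without
shrinking* the shape. With the default 10 iterations a rasterized disc's
perimeter is recovered within 0.7% and a 20x50 px rectangle's area
within 0.1 px²; a Gaussian pre-blur, the obvious alternative, cannot
satisfy both at once (it rounds corners, trading area error for
perimeter error).

### Measurement axes

LL is the extent of the outline along its base-to-tip (midrib) axis and
LW the extent perpendicular to it. The midrib cannot simply be the
principal (major) axis: a broad-ovate leaf is wider than long, so its
midrib is the *minor* axis, and defining LL along the major axis would
make LI < 1 unobservable. We therefore choose between the two principal
axes by bilateral symmetry: a leaf is mirror-symmetric about its midrib
but tapers along it. The reflection-asymmetry score of the radial
function is computed about both axes; the minor axis is selected only
when its asymmetry is both less than half the major axis's and the
major-axis asymmetry is non-negligible (> 0.02), so that ellipse-like
shapes (both axes symmetric) fall back to the major axis. Isotropic
boundaries (circles, squares), whose principal axes are numerically
arbitrary, fall back to the coordinate axes. The tip is the half with
the smaller mean half-width. Extents are measured on the polygon
vertices themselves (equal-arc resampling is used only to stabilize the
axis estimate), because resampling systematically clips extrema.

### Semi-landmarks, alignment, shape PCA

L semi-landmarks are placed at equal radial angles about the area
centroid, clockwise from the midrib axis. L is a free parameter; the
default L = 100 resolves tip and base detail at typical image scales
while keeping the 2L-dimensional shape space manageable. Rays that cut
the boundary more than once (non-star-shaped outlines) resolve to the
farthest intersection and flag the leaf rather than failing.

Generalized Procrustes alignment centers each configuration, scales it
to unit centroid size, and rotates it (rotation only, no reflection) to
the iteratively re-estimated consensus until the mean shape moves by
less than 1e-8. Alignment is idempotent at that tolerance.

Shape PCA runs on the flattened 2L coordinate matrix; the smallest
number of components whose cumulative variance fraction exceeds the
threshold (default 0.96) is retained. Two PCA modes are sensible for
four-leaf data — one PCA per leaf type, or one joint PCA on the
concatenated four-type coordinate block — and both are available by
construction (apply `shapePca` to whichever alignment set is wanted);
per-type PCs feed the single-leaf scans and a joint 4-vector of trait
values or target-PC scores feeds the multi-leaf scan.

### Elliptic Fourier analysis

`efaFit` computes Kuhl-Giardina coefficient quadruples under
chord-length parameterization, in closed form for the piecewise-linear
contour (the DC terms are the arc-length centroid). One consequence of
the chord-length convention is worth stating: the first harmonic of an
eccentric ellipse does *not* reproduce its axis ratio (a 2:1 ellipse
yields a harmonic-1 semi-axis ratio of 1.704, with the remaining
eccentricity spread into higher harmonics); the full descriptor
reconstructs the 2:1 ratio to 1e-3 at 25 harmonics. The test suite
pins the coefficients to an independent exact-integration oracle at
1e-8. The default 25 harmonics captures >99.9% of harmonic power on
leaf-like contours; reconstruction error is non-increasing in the
harmonic count by construction.

Box-Cox normalization (profile likelihood for lambda on [-5, 5], with a
recorded shift when values are non-positive) is applied to shape PCs
before association scans, and Shapiro-Wilk at 0.05 decides which PCs
need it.

## Single-leaf association

The per-leaf-type model is the standard mixed model
Z = mu + X alpha + P beta + eta, eta ~ MVN(0, K sigma_g^2),
epsilon ~ MVN(0, I sigma_e^2). Variants: LM drops structure and
kinship; Q keeps genotype-PCA covariates; QK keeps both. Variance
components are REML-estimated once under the null via the spectral
decomposition of K and a 1-D search over the variance ratio, and reused
for every SNP (the EMMAX approximation): per-SNP re-estimation changes
nothing at scan accuracy while multiplying cost by the variance-fit
count. With K proportional to the identity the two components are
jointly unidentifiable; the fit is flagged (`boundary = TRUE`) and the
GLS scan then reduces exactly to OLS, which the tests assert at 1e-8.
LM is the pipeline default — with both covariate sets available by
flag — because structure diagnostics (lambda_GC, Q-Q) on data of this
design show little confounding to correct.

Missing genotypes are mean-imputed per SNP for association, GRM and
PCA; LD r² uses pairwise-complete observations. GRM (VanRaden-type
standardized relationship matrix) is the model covariance; KING-robust
kinship is computed for QC only, since it may be negative and is not a
valid covariance.

Genome-wide thresholds come from permutation: each of `nPerm`
phenotype reshuffles records the genome-wide *maximum* squared
statistic, and the empirical (1 - alpha) quantile is the critical
value. The maximum-based statistic controls family-wise error (a
per-SNP quantile would not), thresholds are per trait, and the
permutation stream is seeded so a threshold is bit-reproducible.

## Multi-leaf association

Each tree's four leaf values form C_i = (c_i1, ..., c_i4) in canopy
order. At a SNP with genotype groups j = 1..J (J of 2 or 3 observed),
the full model gives each group its own mean 4-vector Theta_j with a
covariance shared across groups, generated by the first-order
structured antedependence model SAD(1):
e_t = phi e_{t-1} + eps_t, eps_t ~ N(0, nu^2), e_0 = 0. The null model
forces Theta_j == Theta, and the likelihood-ratio statistic
LRT = 2 (logL_full - logL_null) flags SNPs whose genotype groups differ
in their canopy profile.

### Closed-form SAD(1) likelihood

Writing the recursion in matrix form, e = L eps with L unit
lower-triangular (L[t,s] = phi^(t-s)), the covariance is
Sigma = nu^2 L L' with det(Sigma) = nu^(2T). For any mean structure
whose MLE is a group mean (exact under a shared covariance), the
profile log-likelihood depends on the pooled within-group
cross-product matrix W only through three band sums (c0 = sum of
diagonal, c1 = sum of first subdiagonal, c2 = sum of the first T-1
diagonal entries), because tr(Sigma^{-1} W) =
(c0 - 2 phi c1 + phi^2 c2)/nu^2 is quadratic in phi. The MLE is exact:
phi = c1/c2, nu^2 = (c0 - 2 phi c1 + phi^2 c2)/T, and
logL = -nT/2 (log 2 pi + 1 + log nu^2). The package therefore does not
run the numerical optimizer a naive implementation would need; the
tests verify the closed form against brute-force MVN density
evaluation (1e-8 on 1,000 random instances) and against Nelder-Mead.
This exactness is also what makes permutation thresholds affordable:
one scan of 1,000 SNPs x 300 trees costs three (n x m)'(n x 11) matrix
products and vector arithmetic, ~4 ms.

Design choices around the scan: phi is unconstrained (SAD(1) is
positive definite for every real phi); genotype groups smaller than 5
are excluded from that SNP's fit (4-vector means on tiny groups are
unstable) and the null likelihood is re-evaluated on the same retained
subset so LRT >= 0 holds identically; individuals missing any leaf
type are excluded (the likelihood is written for complete 4-vectors;
an observed-margins extension is out of scope); population structure
and kinship are deliberately omitted from this model, matching the
single-leaf diagnostics that motivate LM as the default. Permutations
reshuffle whole 4-vectors across trees, preserving the within-tree
covariance under the null. PVE at a SNP is the group-size-weighted
variance of the fitted means over the total phenotypic variance, per
canopy position, with the maximum over positions as the headline
number (per-position values are retained; the summary convention is a
choice, stated here once).

## The synthetic-data generator

The generator defines the package's reference study conditions and is
first-class, tested code. Genotypes: per-SNP allele frequencies uniform
on [0.05, 0.5] (configurable), binomial genotypes, optional
two-subpopulation structure by Balding-Nichols Beta-diverged
frequencies at a configurable Fst, optional uniform missingness
(default 0). Phenotypes: baseline 4-vector plus planted additive QTL
effects per canopy position, plus an optional polygenic value shared
across the four positions (drawn MVN with the realized GRM, scaled so
polygenic_h2 is the fraction of residual variance), plus SAD(1)
residuals via the innovation factorization. Defaults are the reference
null conditions used throughout the checks: 300 trees, 1,000 SNPs,
phi = 0.5, nu^2 = 1, no QTLs, no structure. The baseline
(5, 2.8, 1.4, 0.8) sits on the leaf-index scale of the four classes —
location shifts are irrelevant to every scan statistic, but it keeps
simulated trait tables on a realistic scale for the outline generator.

Outlines: a parametric archetype x(t) = cos t,
y(t) = sin t (1 - taper cos t), tip at +x, with the width axis rescaled
so the realized vertex-extent ratio equals the target LI exactly. The
default taper 0.35 narrows the tip enough that the midrib is
identifiable by symmetry even for broad-ovate targets; taper 0 with
LI = 1 degenerates to a circle, which the trait tests exploit.
Rasterization draws the filled polygon (even-odd scanline) on an RGB
(200, 30, 30) backdrop at 512 px to exercise the full image path.

What the generator does not emulate: linkage disequilibrium beyond
subpopulation structure, within-type replicate leaves per tree (one
leaf per type per tree is emitted; field data may average replicates),
petioles, damaged or overlapping leaves, and lighting variation.
Passing tests therefore demonstrate correctness of the algorithms
under the stated generative model, not robustness to field-photography
artifacts.

## Problem sizes and reproducibility

The shipped checks use desk-scale sizes chosen to make the statistics
sharp enough to falsify the implementation: SAD(1) parameter recovery
at n = 2,000 (50 replicates, phi within 0.05, nu^2 within 10% on the
replicate mean); oracle equivalence on 1,000 random instances;
family-wise calibration on 100 null datasets of 300 x 1,000 at 200
permutations (binomial CI must cover 5%); single-leaf lambda_GC
averaged over 5 null scans of 2,000 SNPs; power on a planted
10%-variance QTL across 100 replicates (top-hit rate >= 95%);
morphometric round trips at LI in {0.8, 1.5, 3, 5}; HWE equality with
an enumeration oracle over every configuration up to 50 individuals.
Every stochastic stage takes an explicit seed, every pipeline stage
derives its stream from the single configured seed, and rerunning a
pipeline with the same configuration reproduces thresholds and scans
bit-for-bit.

## Known limitations

Single-leaf and multi-leaf scans test additive genotype-group effects
only (no dominance parameterization beyond the free 3-group means in
the multi-leaf model, no epistasis). The multi-leaf model ignores
kinship by design; under strong cryptic relatedness its permutation
threshold remains valid for exchangeable trees but the LRT's power
ranking can shift. The LD decay curve is the empirical
a exp(-b d) + c form (the Hill-Weir drift expectation is available by
flag); neither models recombination-rate variation. The star-shape
assumption of radial semi-landmarks fails for deeply lobed leaves —
flagged, not fixed; entire leaves with that geometry need a different
landmarking scheme.
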