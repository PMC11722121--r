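---
title: "Macular OCTA morphometry and mixed-model cohort analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macular OCTA morphometry and mixed-model cohort analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how each stage of the package is defined, which
parameters matter, where open methodological choices had to be fixed, and
what the synthetic validation does and does not demonstrate.

## The measurement problem

En face OCT angiography of the central 3 x 3 mm macula (about 304 x 304
px, 0.0099 mm/px) renders the perfused microvasculature as a bright
filamentous texture around the foveal avascular zone (FAZ). Single
acquisitions are noisy and shifted by residual eye motion, so several
consecutive scans are aligned and combined before quantification. The
quantities of clinical interest are the capillary perfusion and vessel
densities (with the larger arterioles and venules removed), vessel
tortuosity, fractal dimension, vessel calibre, and the FAZ's size and
shape, the last corrected for the optical magnification of the
individual eye. In the cohort setting these per-eye metrics join
clinico-demographic variables in a mixed-model analysis, because many
patients contribute both eyes and eyes within a patient are correlated.

## Imaging chain

**Quality gating.** A frame enters the stack only if its signal strength
index exceeds 50 or its scan quality score exceeds 8/10, as strict
inequalities; a frame carrying neither score is an error.

**Inhomogeneity correction.** The multiplicative illumination bias is
estimated as a heavy Gaussian blur of the frame (default kernel sigma
0.5 mm, i.e. about 50 px — well above the capillary spacing of about
0.09 mm) and divided out, rescaling to preserve the global mean. The
blur uses replicated (not circular) boundaries; for kernels comparable
to the image size it is computed on a decimated grid and resampled,
which changes the estimate by far less than the bias it removes.

**Registration.** Stages run in the fixed order translation, affine,
elastic, and all estimated transforms are composed into a single
coordinate map so the moving frame is interpolated exactly once
(bilinear). The dissimilarity score is the negative normalized
cross-correlation (NCC): it is invariant to the affine intensity
normalization used later, and monotone improvement per stage is part of
the contract. Translation comes from the FFT cross-correlation peak with
parabolic sub-pixel refinement; the affine stage first sweeps a coarse
rotation grid, re-estimating the translation by FFT at every candidate
angle — necessary because the quasi-periodic capillary texture aliases a
pure translation estimate under rotation — and then runs Nelder-Mead
over (shift, rotation, log-scales, shear) on a 2x-decimated grid with a
short full-resolution polish; the elastic stage estimates local translations
on a coarse control grid by block matching (default spacing 32 px,
displacements capped at 3 px), smooths them, and interpolates a dense
displacement field. A parametric B-spline optimisation would satisfy the
same contract; block matching was chosen because it optimises the same
NCC score locally at a small fraction of the cost and is deterministic.
A frame whose translation stage fails to improve the score (epsilon = 0)
while reporting a non-trivial shift is flagged and excluded. The
reference frame is the gated frame with the highest quality score, ties
broken by lowest index.

**Averaging.** Pixelwise mean by default; maximum projection is
available because display-oriented protocols often use it, but all
quantification downstream assumes the mean image.

**Segmentation.** The trained-network binarizer used in some clinical
pipelines is not reproducible from published material, so the package
uses a deterministic classical segmenter: multiscale Hessian vesselness
(scales 0.7/1.1/1.8 px, beta = 1.5, scale-normalized eigenvalues;
response zero where the smaller eigenvalue is non-negative), hysteresis
thresholding (high = Otsu of the response, low = 0.25 x high), and
removal of components under 10 px. Downstream metrics are defined on the
binary mask, so any segmenter meeting the phantom overlap checks (Dice
at least 0.85 on noise-free phantoms) is interchangeable. The scales
bracket the phantom's capillary and arteriole calibres (1.5 to 4.6 px).

**Skeleton and graph.** Zhang-Suen thinning yields 1-px centerlines.
Junction pixels are those with crossing number (0-to-1 transitions
around the 8-ring) of three or more — the crossing number, unlike a raw
neighbour count, does not misfire on the staircase pixels of diagonal
runs. Adjacent junction pixels merge into one node; edges are traced by
walking away from junction clusters along unvisited centerline pixels,
with two guards for 8-connectivity artefacts: the first steps away from
a cluster may not re-enter its fringe, and a dead-ended 1-2 px run whose
tip is not a genuine free end is discarded as junction spill-over.
Isolated cycles become closed self-loop edges. Edge width is the mean of
twice the Euclidean distance transform along the run.

**Strahler ordering and vessel classes.** Orders are defined on trees,
so each connected component is reduced to a breadth-first spanning tree;
chord edges of cycles are excluded from ordering, given order 1 and
flagged. Leaves take order 1; a parent whose children attain maximum
order k takes k+1 when at least two children attain k, else k; an edge
inherits the order of its child-side subtree. The root policy (the
acquisition protocol leaves it open) is automatic: in each component the
widest edge is assumed to be the feeding vessel, and its node nearer the
image border is the root; explicit roots can be supplied. Edges of order
2-4 are arterioles/venules (a strict band: order 5 and above is not AV),
everything else capillary. A user-supplied AV mask can replace the
automatic band to mirror an interactive delineation. On single-tree
phantoms the automatic chain recovers the generating orders almost
exactly; when several trees touch, or a dense capillary mesh connects
them, the spanning-tree reduction of the merged component degrades the
class labels — which is precisely why interactive delineation is common
practice and why the option to inject one exists.

**Spur pruning.** Endpoint-terminated edges shorter than `min_len_px`
(default 5 px) are removed iteratively and pass-through nodes re-merged;
the operation is idempotent at its fixed point.

## Vascular metrics

Perfusion density excludes AV pixels from numerator *and* denominator
(capillary density of the non-AV area). The defining sentence of the
protocol does not say which convention was used; symmetric exclusion
keeps the ratio interpretable as a density on AV-dense images, and a
flag switches to numerator-only exclusion. Vessel density applies the
same ratio to the skeleton, so VD is at most PD by construction.

Mean diameter is `mean(2*dt - 1)` over skeleton pixels, where `dt` is
the mask's distance transform; the `-1` removes the half-pixel border
counted on each side (a w-px ribbon otherwise reads w+1). Fractal
dimension is the least-squares slope of log box counts over dyadic box
sizes 2-64 px; at least three usable scales are required. Both are
reconstructions of under-specified protocol steps and are flagged as
such in the pipeline's decision flags.

Tortuosity method 1 is the arc length over the endpoint chord; closed
loops are rejected and excluded from aggregation. Method 2 is a
composite vessel tortuosity index,
`0.1 * SD_theta * N * M * (L_A/L_C) / L_A`, with `SD_theta` the SD of
the unwrapped tangent-angle sequence in degrees, `N` the number of sign
changes of the turning sequence (critical points), `M` the mean
amplitude between critical points, and `L_A`, `L_C` the arc and chord
lengths; coordinates are lightly Gaussian-smoothed (sigma = 1 sample)
before differentiation. It is zero for straight lines and increases with
both oscillation amplitude and frequency. Class means are unweighted
over edges passing a 10 px length filter.

## FAZ segmentation and shape

The vessel mask is closed with a disc (radius 5 px, enough to bridge
inter-capillary gaps of up to about twice that) and the avascular
connected component containing the fovea seed (default: image centre) is
taken; a seed on a vessel after closing is an error, not a silent
fallback. Area is pixel count times pixel area. Perimeter uses the
Vossepoel-Smeulders step weights (0.980 straight, 1.406 diagonal, -0.091
per corner) plus pi for the half-pixel offset of tracing pixel centres;
on digitized circles and squares this is within about 3% of the true
perimeter, which bounds the acircularity error. Eccentricity comes from
the second central moments of the pixel set (with the 1/12 per-pixel
variance term), the axis ratio from the axis-aligned bounding box
(reported as long/short, at least 1), the acircularity index as
`perimeter / (2*sqrt(pi*area))` — the form consistent with published
values exceeding 1, rather than the reciprocal-square gloss sometimes
printed — and the min/max Feret diameters by rotating calipers on the
boundary's convex hull, widened by 1 px for pixel extent. "Minimum /
maximum FAZ distance" are interpreted as these caliper diameters: for
published group means they bracket the equivalent circular diameter of
the mean area, which centroid-to-boundary radii would not.

Magnification: the modified Bennett scaling `q = 0.01306 (AL - 1.82)`
(AL in mm) gives the linear factor `s = q_eye / q_device` against the
device's assumed axial length (default 23.95 mm, configurable). Linear
metrics scale by `s`, areas by `s^2`, dimensionless shape descriptors
are untouched, and double correction is an error. The fuller
keratometry/refraction Littmann variant is not implemented because its
constants are not published for the target device; axial-length-only
correction is the documented default.

## Synthetic phantoms

The phantom generator is built for testability, not photorealism: every
quantity the pipeline estimates has a generating value. Trees bifurcate
recursively (angle jitter 26-46 degrees, length ratio 0.72, random early
termination at 8%), so the generator's own Strahler bookkeeping — two
children of order k meet in a parent of order k+1 — is checked against
an independent recursion in the tests. Widths are `1 + 0.9 * order` px.
The capillary mesh is a jittered 9 px lattice thinned to hit the target
vessel-pixel density (default 0.42, the scale of published macular
perfusion densities), connected to tree tips, and a terminal capillary
ring is stamped 1 px outside the FAZ ellipse — as in real maculae — so
the avascular region matches the generating ellipse to within
discretization. Tortuosity is injected as a sinusoidal displacement
normal to each chord (endpoint-preserving half-waves, amplitude a
fraction of chord length; defaults 0.10 for AV, 0.20 for capillaries),
so the generating arc/chord ratio follows from dense quadrature; clipped
segments get the ratio of their clipped portion. Rasterization marks a
pixel as vessel iff its centre lies within `width/2 + 0.25` px of a
densified centerline point — an exact geometric rule an independent
brute-force stamper reproduces pixel for pixel. The reference image is
the mask lightly blurred (sigma 0.7 px) on a 0.12 background; frame
stacks add sampled translations (and optional rotations), multiplicative
speckle and additive Gaussian noise, recording the true transforms.

What phantom validation does *not* show: real OCTA speckle is neither
Gaussian nor stationary, projection and motion artefacts are absent, the
capillary plexus is a 3D structure collapsed here to a lattice, and
vessel contrast does not vary with flow. Passing the recovery checks
demonstrates the estimators are correct on their own terms, not that
device images meet the estimators' assumptions.

## Synthetic cohorts

`generate_cohort()` reproduces the study structure exactly: 33 patients,
15 bilateral, 48 eyes, 22 PNP-present assigned exactly (not by Bernoulli
draws), and the published missingness (one HbA1c; two each of DM
duration, LDL, HDL, past anti-VEGF, past steroids). Numeric variables
are drawn group-wise from normal distributions with the published means
and SDs plus a patient-shared intercept whose SD is a fraction (default
0.45, a mid-range within-patient correlation for ocular metrics) of the
pooled SD; values are clipped at physiological floors. Categorical
variables are drawn from the published group frequencies; where a
table's printed percentages are internally inconsistent with its
denominators the *counts* are used and normalised. Cross-correlations
between variables are not modelled beyond the group label and the
patient intercept, because no covariance structure is published; this
means multicollinearity behaviour on real data (e.g. between the two
tortuosity methods) is exercised only through explicitly constructed
fixtures, not through the default cohort.

## Statistical chain

Imputation follows the iterative random-forest scheme for mixed-type
data: mean/mode initialisation, variables swept in increasing
missingness order, each regressed on all others (100 trees), stopping
the first time the relative change criterion rises for both numeric and
categorical sets and returning the previous sweep. Given the seed it is
deterministic.

The univariate screen uses Welch's t test for numerics (the protocol
says only "independent sample t-test"; a pooled-variance switch exists)
and a fully enumerated two-sided Fisher exact test for categoricals
(hypergeometric for 2 x 2; recursive enumeration of all fixed-margin
tables otherwise, summing probabilities at most that of the observed
table with a 1e-7 relative tie tolerance). Variables significant at 10%
are retested with mixed models, as are — regardless of significance —
FAZ area and both capillary tortuosity measures. Note the exact test is
conservative at small n by discreteness, so its realised type-I rate
sits below the nominal level; calibration assertions are therefore made
on the t branch and only an upper bound on the exact branch.

Mixed retests use a per-patient random intercept: REML linear mixed
models for numerics (with Shapiro-Wilk and Levene assumption checks and
the transformation ladder none / sqrt / power 1.05 when requested),
logistic mixed models by adaptive Gauss-Hermite quadrature (15 nodes
default; the log-likelihood is stable to under 1e-3 between 7 and 25
nodes on package fixtures), and a baseline-category multinomial logit
with a single shared normal intercept per patient, estimated by
Gauss-Hermite quadrature with a likelihood-ratio test for the overall
group effect. Singular fits are flagged at a random-intercept variance
below 1e-6; quasi-separation at |coefficient| above 10 on the logit
scale.

Before selection, numeric candidates are pruned at |r| > 0.9: within an
offending pair the member with the larger mean absolute correlation to
the remaining candidates is dropped — the rule that reproduces the
published exclusions on their printed correlations — and PRP is excluded
manually because the outcome is itself an indication for that treatment.
Backward-AIC selection first grows a maximal model (candidates ordered
by single-term AIC, each kept only if the fit still converges), then
repeatedly deletes the term whose removal lowers AIC most, stopping when
no deletion lowers it; AIC comparisons use maximum-likelihood (Laplace)
fits, as REML likelihoods are not comparable across fixed-effect sets.
One consequence worth stating plainly: backward elimination under AIC
retains a pure-noise term whenever its single-degree deviance
contribution exceeds 2 (probability about 0.157 under the null), so with
three noise candidates the expected fraction of runs ending with an
empty model is about 0.84^3 ~ 0.60 — a property of the criterion, shared
by `stats::step()`, not a defect of the implementation.

Classification accuracy uses leave-one-out cross-validation at the eye
level (48 folds), predicting each held-out eye at the population level
(random intercept zero); leave-one-patient-out is available since eyes
are correlated and the protocol does not say which unit was used. The
AUC and its 95% DeLong interval come from pROC; the suite checks the AUC
against an O(n^2) concordance count. The normative stratification
counts eyes against PD > 0.45 ("normal" strictly above) and FAZ area
< 0.3 mm^2 ("preserved" strictly below), excluding rows with missing
metrics and reporting the exclusion counts.

## Problem sizes used by the test suite

Phantom-based checks run mostly on 160 px (1.6 mm) and 120 px grids with
2-3 trees, 50 phantoms for the density oracles, 30 per class for
tortuosity recovery, and 50 seeds for FAZ recovery; mixed-model
simulations use 100-200 patients with two eyes each and 25-50 seeds; the
screening calibration uses 1000 null replicates of a 48-eye table. These
sizes make each recovery distribution tight enough for the stated bounds
while keeping the default suite quick to run; the estimators themselves
are size-agnostic.

## Known limitations

- Strahler classes degrade when distinct trees merge through the
  capillary mesh; supply an AV mask for faithful class assignment on
  such images.
- The elastic registration stage corrects smooth low-amplitude fields
  only (capped at 3 px); severe shear or intra-frame distortion should
  be handled by discarding the frame at gating.
- Tortuosity aggregation is per graph edge (junction to junction), which
  on dense meshes is not identical to per-anatomical-segment
  aggregation; the package reports unweighted edge means.
- The multinomial mixed model assumes one shared random intercept across
  categories; category-specific intercepts are not identifiable at the
  cohort sizes this package targets.
- Fisher enumeration is exponential in table size; it is intended for
  cohort-scale tables (n of a few hundred, small r x c), not for large
  sparse tables.
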