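---
title: "Measuring curvature-driven lipid sorting on buckled bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring curvature-driven lipid sorting on buckled bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvsort)
```

## The problem

A lipid bilayer compressed along one box dimension buckles out of plane,
producing a sustained, spatially varying curvature field. Lipid species
differ in shape, charge and flexibility, and therefore redistribute along
the buckle: cone-like and polyunsaturated lipids accumulate where the
monolayer bends toward their preferred curvature. `curvsort` quantifies
this *curvature partitioning* from coarse-grained (Martini-style)
coordinate frames, and ships a synthetic buckled-membrane generator with
fully known geometry and sorting so that every stage of the pipeline can be
validated against closed-form oracles and parameter recovery rather than
against opaque simulation output.

The bundled system is an asymmetric plasma-membrane mimic of eight species
(POPC, PAPC, POPE, DIPE, DPSM, PAPS, PAP6, CHOL in the registry; PAP6 is a
PIP2 lipid), with 1350 lipids in the outer and 1348 in the inner leaflet.
PAPS and PAP6 occur only in the inner leaflet, as in plasma membranes.

## Geometry of the buckle

Compressional strain is defined from the box lengths along the buckling
axis before (`X0`) and after (`Xi`) compression:

$$\gamma = \frac{X_0 - X_i}{X_0}.$$

The synthetic midplane is a single-period cosine
$z_{\mathrm{mid}}(x) = A\cos(2\pi x / X_i)$ whose amplitude $A$ is solved by
bisection (tolerance $10^{-6}$ nm) so that the arc length over one period
equals $X_0$ — buckling conserves membrane area. A true compressed sheet
follows an Euler elastica, not a cosine; the cosine is chosen because its
derivatives and curvature are analytic, which is what makes oracle testing
possible, and none of the statistics contracts depend on the exact shape.
At $\gamma = 0$ the amplitude is exactly zero.

Each leaflet surface is the midplane offset by $d/2$ along the local unit
normal. By the parallel-curve formula the leaflet curvature is
$\kappa / (1 \mp (d/2)\kappa)$, so an offset surface is regular only while
$(d/2)\,\max|\kappa| < 1$. The default $d/2 = 2$ nm (a typical
coarse-grained half-thickness) satisfies this up to $\gamma \approx 0.35$
for a 40 nm box; at $\gamma = 0.4$ the generator rejects it and a smaller
offset (1.5 nm is used throughout the tests at that strain) is required.
This is a geometric validity constraint, not a tuning knob.

## Signed curvature convention

For a leaflet height function $f(x)$ the pointwise curvature is

$$C(x) = \frac{f''(x)}{\bigl(1 + f'(x)^2\bigr)^{3/2}},$$

in nm$^{-1}$. The sign of the outer-leaflet values is inverted, so that for
*both* leaflets a region that is concave as seen from that leaflet's own
side is negative and a convex region positive. A consequence used as a
property test: mirroring all z coordinates swaps the leaflet labels but
leaves the signed per-lipid curvature table invariant.

## Spline fit

Each leaflet's headgroup-bead positions are collapsed onto the XZ plane
(the buckle is uniaxial) and fitted with a penalized cyclic cubic
regression spline (`mgcv`, basis `"cc"`), which is periodic with matching
derivatives at the seam and C2-continuous, as the curvature formula
requires. Periodicity is handled by the basis itself, not by duplicating
data.

Numerical choices:

* **Basis dimension**: one knot per 1.5 nm, clamped to [10, 40]. Refining
  the basis changes per-lipid curvature by well under 2% RMS on noiseless
  surfaces (tested).
* **Smoothing**: selected by GCV. On noiseless data GCV collapses toward
  interpolation and the fitted surface tracks the analytic leaflet surface
  to better than 0.05 nm; with placement noise the residual RMS tracks the
  noise scale. An explicit residual-RMS target was considered and rejected:
  it would force distortion onto noiseless data, contradicting the
  surface-recovery oracle. The `roughness` scale (default 0.5 nm) is kept
  as a QC threshold: frames whose residual RMS exceeds 5x the scale are
  flagged, not dropped.
* **Trajectory mode**: smoothing is selected on the first frame per leaflet
  and held fixed for the rest (`reuse_sp = TRUE`), which stabilizes the
  estimator across frames and is several-fold faster; per-frame selection
  is available.
* **Derivatives** are evaluated on the spline basis by central differencing
  of the linear-predictor matrix with a $10^{-3}$ nm step; for a cubic
  basis the associated error is orders of magnitude below the 1% oracle
  tolerances.
* **Evaluation point**: each lipid's curvature is evaluated at its own
  headgroup x position, not at the nearest knot.

The bead that defines the surface is configurable per species (phosphate
bead for phospholipids, hydroxyl bead for cholesterol by default), because
the observed curvature depends on which bead is taken to represent the
surface.

## Leaflet assignment

A buckled membrane's leaflets interleave in global z, so lipids are
classified against a *local* midplane: headgroup z values are averaged in
2 nm x bins and interpolated periodically at each lipid's x. Labels are
recomputed every frame (sterols can flip between leaflets). On synthetic
buckled frames up to $\gamma = 0.3$ the assignment agrees with the
generator's ground truth for more than 99% of lipids (tested).

## Sorting statistics

All statistics use 4-block averaging: the frame sequence is split into four
contiguous equal blocks (trailing remainder dropped with a warning), the
statistic is computed per block, and the across-block mean and sample SD
are reported.

* **Curvature distributions** per leaflet: density-normalized histograms,
  bin width 0.05 nm$^{-1}$.
* **Enrichment profiles**: for species $s$ in curvature bin $b$,
  $F_s(b) = \bigl(n_s(b)/n(b)\bigr) / \bigl(N_s/N\bigr)$ — the species'
  share of the bin divided by its leaflet share, so $F = 1$ means no
  sorting. This normalization was chosen over the raw in-bin fraction
  because it makes slopes independent of leaflet composition and centers
  "no sorting" at 1; the identity $\sum_s (N_s/N) F_s(b) = 1$ holds exactly
  per bin and is asserted in the tests. Bins whose mean per-frame occupancy
  is below 5% of the per-frame leaflet lipid count are masked from all
  fits.
* **Partition slope**: unweighted OLS of $F_s$ versus bin-center curvature
  over unmasked bins, fitted per block; the across-block mean ± SD is the
  reported coefficient (units nm). The fit is per block, consistent with
  the block ± SD convention, and the uncertainty is the block SD, not the
  OLS standard error.
* **Per-species mean curvature**, **extreme-curvature fraction**
  (|C| > 0.1 nm$^{-1}$ by default) and **localization profiles** along the
  buckle (1 nm x bins, per-species rows normalized to 1; species absent
  from a leaflet are flagged).
* The biologically relevant curvature window (~0.02-0.13 nm$^{-1}$) is a
  reporting filter for users, not an analysis step.

## Contacts and descriptors

Two lipids of the same leaflet are in contact in a frame when any
bead-bead distance is below 1.0 nm (minimum image laterally); a pair
counts once per frame. Counts per species pair are averaged over frames
and normalized by the random-mixing expectation
$E(i,j) = T f_i f_j (2 - \delta_{ij})$ with $T$ the total mean contacts and
$f$ the leaflet fractions, so ideal mixing gives 1 in every cell — a
contract verified by label-permutation tests. Contacts are intra-leaflet
only; the attractive-vs-repulsive origin of contact preferences is out of
scope.

Static descriptors come from the species registry (bead count as a
molecular-volume proxy, head:tail bead ratio with headgroup + linker beads
counted as "head", unsaturation fraction). Dynamic descriptors are the P2
tail order parameter, measured against the local spline normal (global z
is meaningless on a buckled membrane; on a flat one the two coincide,
which is tested to machine precision), and the splay angle between the two
tail end-to-end vectors (single-tailed species are flagged not
applicable). Descriptor-curvature association uses Pearson correlation
with an explicit exclusion list (cholesterol is the usual outlier).

## The synthetic generator

`sample_frame()` draws one equilibrium configuration: lipid positions
uniform in arc length along each leaflet surface, species assigned by a
categorical draw with probability $\propto f_s \max(0, 1 + s_s C(x))$
renormalized at each x, where $s_s$ is the imposed enrichment slope and
$C$ the analytic signed leaflet curvature. The headgroup bead sits on the
surface with Gaussian z noise (`sigma_z`, default 0.3 nm — a typical
coarse-grained headgroup roughness; no reference value exists for this
knob), remaining beads are laid inward along the local normal at 0.3 nm
spacing, and y is uniform. When every slope is exactly zero the integer
composition counts are placed exactly (a permutation, not a multinomial),
which makes null-control tests sharp. The recorded ground truth per lipid
is its leaflet, headgroup x, and the signed *leaflet-surface* curvature at
the placement point — the covariate the analysis pipeline estimates.

Frames are independent draws; there is no autocorrelation. This means
block averaging is exercised mechanically but blocks are trivially
independent, which is exactly what makes recovery tests exact. Real
trajectories are autocorrelated, so passing tests here say nothing about
effective sample sizes in real data. Other features of real membranes the
generator does not emulate: thermal undulations in y, protrusions,
flip-flop dynamics, thickness variation with curvature, and any coupling
between species beyond the imposed single-lipid enrichment.

Per-frame seeds are drawn from R's RNG seeded with the master seed, so
results are bit-reproducible in R given the master seed (cross-language
reimplementations can match statistics, not bits).

## Statistical resolution of slope recovery

The linear enrichment model is identifiable from
$N_{\mathrm{tot}} f_s \mathrm{Var}(C)$ effective observations. At the
bundled study conditions — 1350 lipids per leaflet, 400 independent frames,
$\gamma = 0.1$ (leaflet curvature range about $\pm 0.16$ nm$^{-1}$) — the
Fisher-information bound on the slope SE for a 2%-abundance species is
about 0.1, and the binned per-block OLS estimator realizes about 0.19; for
a 12%-abundance species about 0.08. Recovered slopes are unbiased (the
estimator agrees with the generator's own maximum-likelihood fit on the
same data, which is how the tests check it), but a single 400-frame run of
a rare species carries sampling noise of that order. Users who need
tighter recovery should scale `n_frames` accordingly (SE scales as
$1/\sqrt{n}$).

One systematic effect is part of the model rather than the estimator: with
the renormalized categorical placement, the bin totals in the enrichment
denominator carry the tilted species too, so the expected recovered slope
is $s_s - \sum_j f_j s_j$ to first order. For a rare species this is
$s_s$ to within 0.01; imposing a slope on a 12% species attenuates the
expectation by about 12%, and the recovery tests compare against this
first-order expectation, not naively against $s_s$.

Problem sizes used by the shipped tests: module tests run 4-13 frames on
small compositions; the end-to-end checks use 400-frame runs for slope
recovery, twenty 80-frame runs for the null control, and one 80-frame
$\gamma = 0.4$ run for the symmetric-control comparison.

## Known limitations

* One curve per leaflet per frame: curvature is resolved along x only; no
  2D curvature tensors or mean/Gaussian curvature maps.
* The cosine buckle is not an elastica; occupancy patterns of extreme
  curvature bins at $\gamma = 0.4$ may differ from a real buckle's.
* The spline smoothing level materially affects the extreme-curvature
  tails of the distributions; it is exposed (`k`, `sp`, `roughness`) rather
  than hidden, and tail-sensitive conclusions should be checked across
  settings. At strains where the leaflet surface is nearly cusped
  (curvature radius below the knot spacing), the fixed knot grid also
  introduces a knot-phase artifact: features on versus between knots are
  resolved slightly differently, which can break exact leaflet symmetry in
  the far tails. Use the densest basis (`k = 40`) for such geometries.
* GRO is the only coordinate format with a bit-exact contract; other
  formats must be converted upstream.
* Bending moduli, spontaneous-curvature coefficients and free-energy
  estimates of sorting are out of scope.
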