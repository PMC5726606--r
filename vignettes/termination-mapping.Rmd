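---
title: "Termination mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Termination mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tractterm` maps where white-matter tracts terminate on the grey–white
interface (GWI) of a lobe and tests whether those termination territories
overlap functional-domain maps beyond chance.  This vignette documents the
model each stage implements, the parameters that matter, what the
synthetic phantom does and does not emulate, and the choices made where
the design was genuinely open.

## The pipeline stage by stage

### Seeds and exclusion mask

The seed set is the set of white-matter voxels on the external surface of
the WM mask — voxels with at least one *face-adjacent* (6-neighbourhood)
voxel outside the mask, with the grid boundary counting as outside —
intersected with a lobe mask.  Face adjacency is the conservative surface
definition on a voxel lattice; 26-connectivity is available as an option
(`extract_gwi(..., connectivity = 26)`) since the convention is not
universal.  Everything outside the WM mask is the tracking exclusion mask:
this prevents streamlines from "jumping" sulcal boundaries through
cortex or CSF and from propagating within cortex.

### Streamline propagation

From each seed voxel centre, `n_streamlines` polylines are stepped at
`step_mm` through the per-voxel orientation field:

* the direction at each step is drawn from the current voxel's
  orientation distribution (nearest-voxel lookup — per-step interpolation
  between voxels is deliberately not attempted; see *Limitations*);
* the draw is sign-aligned to the previous direction (dot product ≥ 0) to
  prevent spurious reversals; the very first step takes a uniform random
  sign, so both directions out of a GWI seed are explored;
* propagation stops on entering the exclusion mask (the first excluded
  point is **retained**, so the grey-matter voxel a streamline terminates
  in is recorded), when arc length would exceed `max_length_mm`, or when
  the angle between the current direction and the direction one voxel of
  arc earlier reaches `curvature_limit_deg`.

Defaults: 10,000 streamlines/seed, 0.5 mm steps, 500 mm cap, 180°
curvature limit (at 180° only exact reversals stop propagation — the
permissive standard).  With 0.5 mm steps in 2 mm voxels no voxel along
the path can be skipped, so visitation uses point-in-voxel membership; a
streamline increments a voxel's count at most once however often it
re-enters.  No distance correction is applied.

Randomness is a deterministic counter-based scheme: each streamline's
generator is seeded by hashing (seed, subject, seed-voxel, streamline
index), so any single streamline is bit-reproducible in isolation and
results do not depend on execution order or parallel scheduling.

### Termination maps

For seed voxel $x$ and tract $y$ with body ROI $R_y$, the raw intensity is
$T_y(x) = \#\{\text{streamlines from } x \text{ intersecting } R_y\}/n$,
assigned at the seed's own voxel.  "Intersecting" means any sample point
falls in an ROI voxel; a per-ROI-voxel criterion collapses to the same
count once a streamline counts only once.  Subject maps are smoothed
(Gaussian, `fwhm_mm = 5` mm, separable discrete kernel, SD
$= \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis, zero boundary, no mask
renormalisation — shared attenuation cancels in the rank-like pairwise
statistics), then averaged across subjects, and the group map affinely
rescaled to $[0,1]$.  The order is smoothing → averaging → rescaling, and
the statistics consume the smoothed **un-rescaled** subject maps
(`use_smoothed = FALSE` switches to raw proportions).  A constant map
rescales to all zeros with a warning.

### Pairwise evidence

For ordered tracts $(A, B)$ and subject difference maps $d_s = A_s - B_s$,
the statistic at each voxel is the one-sample $t$ of $d$ over subjects.
The null flips the sign of entire subject difference maps; familywise
error over the analysis mask is controlled by the permutation distribution
of the maximum statistic, and significance additionally requires
$p_{\mathrm{FWE}} < \alpha/m$.  When $2^{n} \le$ `n_permutations`, all
sign patterns are enumerated and the p-values are exact (at $n = 12$
subjects: 4096 patterns); otherwise patterns are sampled with the identity
flip included.  Zero-variance voxels (detected with a relative tolerance
of $10^{-12}$ of the voxel's sum of squares) take statistic 0 and are
never significant.  Tests are one-sided ($A > B$), variance smoothing and
cluster statistics are deliberately out of scope.

The Bonferroni divisor is open in principle: it could count the $T-1$
comparisons per tract, all $T(T-1)$ ordered pairs, or pairs × hemispheres.
The default is all ordered pairs (42 for 7 tracts, 6 for the 3-tract
phantom), the most conservative of the per-map options; it is a plain
argument (`m_bonferroni`), never silently fixed.

Summing a tract's significant wins gives its evidence map on 0..$T-1$.
The termination ROI keeps the two highest values $\{T-2, T-1\}$ (with an
alternative `"max"` rule keeping $T-1$ only, used for secondary
subdivisions); an empty ROI is a legitimate outcome — a tract may have no
voxel with the required evidence.  ROIs can be subdivided at a coronal
world plane (default $y = -27$ mm) and an explicit superior boundary
(z-plane or mask): phantoms have no gyri, so an anatomical
superior/inferior criterion must be supplied by the caller.

### Overlap statistics

For termination ROI $A$ and binary domain map $B$,
$P = |A \cap B| / |A|$ (exact integer arithmetic).  The null redraws
$|B|$ grey-matter voxels uniformly *without replacement* 10,000 times;
when $A$ lies inside the grey-matter mask this null is hypergeometric
with mean $|B|/|\mathrm{GM}|$, which the tests exploit as a closed-form
oracle.  A cell is reported only when $P$ strictly exceeds the
$1-\alpha/m$ empirical null quantile, with $m$ defaulting to the number
of cells tested.  The uniform null carries no spatial smoothness, which
makes it anticonservative relative to a smooth-map null: a real
functional map is spatially coherent, so its chance overlap with a
compact ROI is more variable than independent voxel draws suggest.
Hemispheres can be tested separately by splitting every mask at world
$x = 0$.

## The phantom: what it emulates, and what it does not

The generator builds, per subject, disjoint WM/GM compartments from
parametric tract curves: WM is the tube of voxels within
`corridor_radius` (4 mm) of a curve, GM a shell of `gm_thickness` (4 mm)
around it, the orientation at each WM voxel is the tangent of the nearest
curve point, and ground-truth termination patches are the tract's surface
voxels within `patch_radius` of each curve end.  The default layout is
three well-separated straight tracts on a 40×48×40 grid of 2 mm voxels;
the lobe mask (the analysis region) is the union of 10 mm balls around
each tract's designated lobe end.  `patch_radius` defaults to the lobe
radius: the ground-truth termination zone of a tract *within the analysis
lobe* is exactly its GWI inside the lobe, so a narrower patch would
mislabel genuinely terminating interface voxels.

Orientation noise perturbs the tangent by a rotation whose angle is
half-normal with SD `dispersion` (degrees) and whose axis is uniform in
the plane perpendicular to the tangent, so the angular deviation from the
tangent *is* the half-normal draw — one intuitive parameter, directly
checkable against the half-normal mean $\sigma\sqrt{2/\pi}$.
Inter-subject variability is Gaussian jitter of the curve control points
(`subject_jitter`, mm).  Its default, 1 mm (half a voxel), is a free
choice — anatomical variability is not quantified in a way that pins it
down — and it is a plain spec field, not a constant.  Functional-domain
maps are binary balls on the GM∪GWI support adjusted to cover an exact
target fraction of a named tract's truth patch (±1 voxel of rounding).

What the phantom does **not** emulate: diffusion signal, b-vectors, or
bootstrap-derived orientation distributions (orientation uncertainty is
parametric); crossing-fibre geometry (corridors may overlap but each WM
voxel carries a single orientation); gyrification, partial volume, or
registration error (everything lives in one common space); realistic
seed counts (the default lobe GWI is ~170 voxels/subject, where a real
temporal lobe at 2 mm gives ~3000 — the full-size analysis would behave
identically but slower).  Passing tests therefore demonstrate the
correctness and calibration of the *pipeline machinery*, not robustness
to acquisition artefacts or anatomical complexity.

## Group-level conventions

Subject phantoms share one grid, so "normalisation" is the identity; the
group analysis mask is the **majority-vote** GWI (voxels that are
interface in at least half the subjects).  A union mask would include
voxels that are interface only under one subject's jitter; such halo
voxels carry smoothed signal in every subject and would inflate evidence
ROIs with a one-voxel rind.  For the same reason, ground-truth recovery
is scored against the cohort-level truth — group-mask voxels within the
tract's termination ball — which reduces exactly to the template's
surface patch when jitter is zero.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based; world coordinates are mm with a diagonal
  RAS voxel-to-world mapping; points bin to the voxel with the nearest
  centre.  All planes (e.g. $y = -27$) are world mm.
* Orientation vectors are unit within $10^{-6}$; step lengths are exact
  to $10^{-9}$.
* Ties in the orientation-field assignment of overlapping corridors go to
  the nearest curve (first index on exact ties) and the overlap count is
  reported in the phantom's metadata.
* Empty WM → empty seed set with a warning; empty ROI → overlap
  proportion is an error (undefined), while an empty *evidence* ROI is
  skipped with a warning in the overlap matrix; constant maps rescale to
  zero with a warning; fewer than 2 subjects or a domain size larger than
  the grey-matter mask are errors.
* NIfTI volumes are written as int32/float64 so write→read round trips
  are bitwise; `.tck` tractograms use Float32LE per the format.

## Problem sizes used in the tests

The shipped tests run the full pipeline at 12 subjects × ~170 seeds ×
1000 streamlines/seed with exhaustive (4096-pattern) permutation
inference and 10,000-draw overlap nulls; unit tests use small constructed
grids and corridors where expected values are computable by brute force
(exhaustive sign-flip enumeration, 6-neighbour surface scans, closed-form
Gaussian kernels, hypergeometric moments).  These sizes were chosen so
the whole suite completes in a few minutes while every statistical check
retains Monte-Carlo error well below its assertion tolerance.

## Known limitations

* Nearest-voxel orientation lookup (no sub-voxel interpolation of the
  orientation distribution) is a deliberate simplification; at 0.5 mm
  steps in 2 mm voxels it changes paths only near compartment boundaries.
* The uniform random-voxel overlap null ignores spatial smoothness (see
  above); a contiguous-blob null is a natural extension and the
  architecture (null draws as a plain function) leaves room for it.
* Binary domain maps discard the magnitude of the underlying statistical
  maps; only their support enters the overlap statistic.
* The evidence scale depends on the tract set: adding or removing a tract
  changes every map's ceiling ($T-1$) and the Bonferroni divisor.
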