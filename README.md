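# tractterm

Where do white-matter tracts terminate on the cortex, and what do those
cortical territories do?  `tractterm` implements a voxelwise pipeline for
answering that question with probabilistic tractography: it seeds
streamlines from every voxel of the grey–white interface (GWI) of a lobe,
asks for each seed what fraction of its streamlines joins each tract of
interest, turns those fractions into statistical *termination maps*, and
finally tests whether the best-evidenced termination territory of each
tract overlaps functional-domain maps more than chance.  Because no public
diffusion data accompany this design, the package ships a synthetic
volumetric phantom generator with known tract geometry and ground-truth
terminations, so the whole pipeline is testable end to end.

It is aimed at researchers who work with diffusion-MRI tractography and
want a small, fully reproducible, testable reference implementation of
termination mapping and its permutation statistics.

## The method

**Seeding and tracking.** The seed set is every white-matter voxel with a
face-adjacent neighbour outside the WM mask, intersected with a lobe mask
(the GWI).  From each seed voxel centre, `n` streamlines (default 10,000)
are propagated at 0.5 mm steps by sampling per-voxel orientation
distributions, stopping on entering the exclusion mask (the complement of
WM; the first excluded point is retained so grey-matter terminations are
recorded), at 500 mm of arc, or when the direction change over one voxel
of trailing arc reaches the curvature limit (180° by default, i.e. only
exact reversals).

**Termination maps.** For seed voxel *x* and tract *y* with body ROI
*R_y*, the raw termination intensity is

&nbsp;&nbsp;&nbsp;&nbsp;*T_y(x)* = (# streamlines from *x* intersecting *R_y*) / *n*,

so 1000 of 10,000 streamlines gives 0.1.  Subject maps are smoothed with a
5 mm FWHM Gaussian, averaged across subjects, and the group map rescaled
to [0, 1]; the un-rescaled maps feed the statistics.

**Evidence maps.** For every ordered tract pair (A, B), the paired
difference maps are tested voxelwise with a one-sample t statistic whose
null is generated by sign-flipping whole subject difference maps;
familywise error over the analysis mask is controlled with the
maximum-statistic distribution, plus Bonferroni correction across the
pairs (exhaustive enumeration of all 2^n sign patterns when that is
cheaper than sampling).  Summing a tract's significant wins gives its
*evidence map* on a 0..T−1 scale (with 7 tracts: 0–6, where 6 = greater
than all other tracts); the tract's termination ROI keeps the two highest
values (T−2, T−1).

**Overlap statistics.** For termination ROI *A* and binary domain map
*B*, the overlap proportion is *P* = |A ∩ B| / |A|.  Its null is built by
drawing |B| grey-matter voxels uniformly without replacement 10,000 times;
a cell of the tract × domain matrix is reported only when *P* exceeds the
1 − α/m empirical null quantile (Bonferroni over the m cells tested).

## Worked example

A 12-subject synthetic cohort with three tracts whose termination patches
are known, and two functional-domain maps planted to overlap the patches
of tracts `alpha` and `beta` at 70%:

```r
library(tractterm)
cfg <- pipeline_config(
  phantom  = list(n_subjects = 12),
  tracking = list(n_streamlines = 1000),
  rng_seed = 42)
study <- run_pipeline(cfg)
summary(study)
```

```
termination study: 12 subjects, tracts alpha, beta, gamma
seeds per subject: 175, 167, 164, 179, 157, 167, 172, 172, 165, 171, 184, 162 (analysis mask 159 voxels)
evidence ROI sizes: alpha=56 beta=51 gamma=52
 tract dice argmax_in_truth argmax_in_roi
 alpha    1            TRUE          TRUE
  beta    1            TRUE          TRUE
 gamma    1            TRUE          TRUE
<overlap_matrix> 3 ROI(s) x 2 domain(s), alpha 0.05 Bonferroni-corrected over 6 tests
cells show the overlap proportion where significant:
      domain_alpha domain_beta
alpha 0.68         .
beta  .            0.69
gamma .            .
```

Reading this: each tract's evidence ROI recovered its ground-truth
termination patch exactly (Dice 1), the group map peaks inside the truth
patch, and the overlap matrix is filled only on the planted tract–domain
pairs, at close to the planted 70% overlap — tract `gamma`, which was
given no domain, shows no significant cell.  `run_pipeline(cfg, out_dir =
...)` additionally writes group/evidence maps as NIfTI, the overlap matrix
as TSV/JSON, and a JSON manifest.  A thin command-line wrapper lives at
`inst/cli/tractterm` (`phantom`, `gwi`, `overlap`, `run`).

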