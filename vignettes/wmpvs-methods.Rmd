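---
title: "Quantifying white-matter perivascular spaces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white-matter perivascular spaces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmpvs)
```

## The measurement problem

Perivascular (Virchow-Robin) spaces are thin fluid channels around
penetrating brain vessels. On clinical MRI they appear hyperintense on
T2-weighted and hypointense on T1-weighted images, linear or punctate
depending on whether they run parallel or perpendicular to the axial
acquisition plane. Their burden in white matter is a candidate marker of
glymphatic function, and case-control studies compare it between clinical
groups — here, a paediatric autism-spectrum cohort against neuropsychiatric
non-ASD controls.

The practical obstacles are (i) the extreme anisotropy of routine
paediatric protocols (0.4-0.8 mm in-plane, 4.4 mm slices), which makes the
structures thinner than a slice, (ii) scanner bias fields that defeat any
fixed intensity threshold, and (iii) visual grading's poor sensitivity to
sub-3-mm calibres. The pipeline in this package addresses these with an
intensity-normalized local-contrast detector and a per-slice counting
scheme that never attempts 3D volumetry.

## The subject-level pipeline

`run_subject()` executes, in order:

1. **Adaptive denoising** (`denoise_adaptive`) of both volumes in native
   space, before any resampling.
2. **Rigid registration** (`rigid_register`): the T2 is aligned to the T1
   grid by maximizing normalized mutual information over a coarse-to-fine
   schedule; interpolation is trilinear for intensities, nearest for masks.
   A known transform may be supplied to bypass optimization.
3. **White-matter mask**: externally produced (preferred) or the
   phantom-grade intensity-clustering fallback (`segment_wm_fallback`);
   eroded by one voxel (`erode_mask`) so boundary partial-volume voxels
   never enter the statistics.
4. **Uniformization** (`uniformize_wm`): a low-order polynomial
   multiplicative bias field is fitted to WM intensities (robust to the
   bright PVS minority via iterative trimming), divided out, and the WM
   median is rescaled to exactly 1000. The fixed anchor is what gives the
   detection threshold a meaning.
5. **Local intensity-difference map**
   (`neighborhood_difference_map`): each in-mask voxel's value is its
   intensity minus the mean of its surrounding voxels — by default the
   in-plane 3x3 ring of 8 neighbours.
6. **Thresholding** (`detect_pvs_voxels`): a voxel is a WM-PVS voxel iff
   its difference value is strictly greater than 60 (6% of the WM anchor).
7. **Per-slice clustering** (`label_clusters_per_slice`): 8-connected
   components within each axial slice; clusters never span slices.
8. **Summary** (`summarize_pvs`): PVS voxel count, WM-normalized volume
   (both are reported; volumes are voxel counts because the slice is
   thicker than the structure), per-slice cluster counts, the maximum
   per-slice count, the 5-point grade (0; 1-10; 11-20; 21-40; >40), and the
   enlargement flag (at least 3 clusters with perpendicular diameter above
   3 mm).

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 60 | local-contrast cut on the uniformized scale (WM median 1000) |
| `target_level` | 1000 | WM median after uniformization |
| `erosion_iterations` | 1 voxel | boundary exclusion before detection |
| `neighborhood` | in-plane ring, radius 1 | "surrounding voxels" of the difference map |
| grade bins | 0 / 1-10 / 11-20 / 21-40 / >40 | 5-point scale on the max per-slice count |
| enlargement | 3 clusters > 3 mm | minor side of the minimum-area in-plane box |

### Open choices and how they were fixed

Several operational details are not pinned down by the method's verbal
description; the package fixes each one explicitly and records it in the
per-run provenance:

- **Neighbourhood of the difference map.** With 4.4 mm slices the
  through-plane neighbours are not comparable tissue, so the default
  neighbourhood is the in-plane 8-neighbour ring; a 3D mode and larger
  radii are available. Neighbours outside the image are excluded from the
  mean; neighbours outside the WM mask are *included* by default (they are
  the tissue the PVS contrasts against), with a flag for the opposite
  convention.
- **Threshold scale.** 60 is interpreted on the uniformized scale. The WM
  median is anchored at 1000 — the convention of the standard
  uniformization tooling this stage emulates — so 60 is 6% of WM level.
- **Erosion connectivity.** Face-connected (6-neighbour) 3D erosion by
  default; an in-plane (4-neighbour, per-slice) mode exists because one 3D
  erosion removes an entire 4.4 mm slab from each mask face, which is
  aggressive for thin compartments.
- **"Highest number of PVS in a single slice"** is read as the per-slice
  *cluster* count, clusters being the method's operational counting unit.
- **Enlargement diameter** is the smaller side of the minimum-area
  bounding rectangle of the cluster's in-plane pixels (plus one voxel, so
  an n-pixel row spans n voxels), i.e. the diameter perpendicular to the
  cluster's main axis. A thin diagonal cluster is therefore *not* wide,
  which an axis-aligned box would get wrong.
- **Filtering order.** Denoising runs in native space before registration
  resampling; the order is logged. Non-finite intensities inside the mask
  abort with a named error rather than being silently dropped.

## The denoiser

The adaptive filter is a per-slice non-local-means with its strength tied
to a noise estimate taken from the volume itself (median absolute
deviation of the in-plane high-pass residual). Two additions matter for
this application:

- the expected noise contribution (2 sigma^2) is subtracted from patch
  distances, so flat regions average aggressively;
- a **centre-difference guard** multiplies the weight down when the two
  centre pixels differ by much more than the noise, *gated on
  adjacent-slab support*: the guard only engages where the same in-plane
  position on a neighbouring slice also shows local contrast. A
  through-plane PVS continues across slabs, so its cross-section is
  protected; an isolated noise spike has no such support and is averaged
  away. In-plane (linear) structures need no guard: their patches are
  intrinsically dissimilar from flat background.

This design preserves a single-voxel tube at a contrast-to-noise ratio of
10 essentially unchanged while halving background variance (both are
asserted by tests). At a contrast-to-noise ratio near 3 — the half-filled
partial-volume voxel at 5% noise — preservation necessarily degrades:
distinguishing a one-voxel structure at 3 sigma from a noise spike is not
statistically possible, whatever the filter.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds an ellipsoidal white-matter compartment inside
GM and CSF rims (no gyrification — the pipeline only needs a WM interior),
plants straight cylinders with analytic-distance partial-volume rendering
(the fraction of each voxel inside the cylinder is estimated on a sub-voxel
grid), and only then applies a smooth multiplicative bias field and noise
(Gaussian by default, Rician optionally — at the simulated SNRs the
difference is negligible). The T2 volume is acquired through a configurable
rigid misalignment, which registration must recover. Ground truth is the
set of voxels at least half filled by a tube, and the per-slice true counts
derive from that mask.

Lattice placement (`snap_to_slices = TRUE`) snaps through-plane tube
endpoints to slab boundaries and centres to the in-plane voxel lattice.
This makes the half-volume ground truth *unambiguous*: every intersected
slab holds a voxel with fraction well above one half, and no slab is
grazed. Without snapping, a tube can cross a slab so peripherally that
truth (fraction >= 0.5) and detection (contrast > 60, reached near
fraction 0.2) legitimately disagree — a boundary ambiguity of the truth
definition, not of the method.

Calibre matters the same way. The package default radius range
(0.3-1.2 mm) deliberately straddles the visibility boundary: below about
half an in-plane voxel (0.4 mm radius at the 0.8 mm grid) the maximal
partial-volume fraction can stay below 0.5 and a structure is invisible to
the ground-truth definition while still nudging the detector. The
*recovery* suites therefore use 0.6-1.2 mm — calibres resolvable at the
acquisition grid, whose centre voxels are fully inside the tube — because
they measure the pipeline, not the partial-volume ambiguity.

Problem sizes used throughout (128 x 128 x 24 voxel phantoms, 20 cases per
condition, 1000-replicate null calibrations, 200-replicate power runs)
were chosen as the smallest batches whose pass/fail behaviour is stable
across seeds.

What passing phantom tests does **not** show: performance on real
paediatric MRI with gyral WM geometry, flow artefacts, motion, or
pathology (gliosis mimics PVS contrast and is explicitly outside the
automated method's scope — the study handled it by neuroradiological
reading). The WM fallback segmentation is phantom-grade only; clinical use
assumes an externally produced mask.

## The cohort simulator

`generate_cohort()` draws subject records with the study's covariate
structure: 64 ASD / 72 controls, male fractions 0.672 / 0.556, severity
levels distributed 10/18/36, comorbidity rates taken from the published
frequency tables. WM-PVS volume is lognormal, anchored at the published
female median (425 voxels; log-sd 0.6 back-computed from the printed IQR),
with multiplicative effects: male 1.4 (596/425), young-ASD 1.9 (795/422),
1.25 per severity level ((751.5/488.5)^(1/2)), and 1.3 for insomnia. The
max-slice count is the volume divided by 20 — a scale fixed by the
published grade-stratified medians (161 voxels in grade 1 maps to 8
counts, the cohort median 545 to 27, the grade-4 median 1114 to 56) — with
lognormal noise of sd 0.25, which produces roughly 15% adjacent-grade
confusion and guarantees a positive grade-volume rank correlation without
making grade a deterministic function of volume.

These defaults are the simulated study conditions; analyses that need a
null simply set the effect parameters to 1. One consequence worth knowing:
the effect sizes are back-computed from *marginal* subgroup medians, so
stacking them multiplicatively (a young, severe, male ASD subject receives
all of them) pushes the simulated cohort's overall median above the
published one — the generative model tests the analysis machinery's
ability to recover effect directions, not to reproduce every marginal
summary simultaneously.

## The statistics layer

All inference is intentionally plain: Mann-Whitney (exact for two groups
of at most 20 without ties, otherwise the normal approximation with tie
correction and no continuity correction) or Kruskal-Wallis for
quantitative variables; Pearson chi-square *without* continuity correction
or Fisher's exact test for categorical ones, selected by the classic
any-expected-count-below-5 rule with a manual override — the published
tables are consistent with uncorrected chi-square on the large 2x2 tables,
but the test used per row is not stated, so every report records which
test ran; Spearman correlation (asymptotic, tie-corrected) between MRI
measures; Shapiro-Wilk only to justify the nonparametric choices.
Quartiles use linear interpolation (R type 7), percentages round half-up
to one decimal (56.25% prints as 56.3), p-values display at two
significant figures with a `<0.0001` floor, and significance is a plain
p < 0.05 — deliberately with **no** multiple-testing correction and no
multivariable adjustment, because the analysis being reproduced applies
none; adding either would change the published comparisons, so the package
surfaces the raw decision per row instead.

Missing data are deleted row-wise per variable and every percentage is
printed with its denominator, which is how reduced denominators (e.g.
IQ tested in a subset) stay honest.

## Numerical notes

- Tube separation uses a closed-form segment-segment distance with a
  *relative* parallelism tolerance; an absolute tolerance misclassifies
  near-parallel segments and produced overlapping tubes in early testing.
- The polynomial bias fit stops trimming when residuals hit numerical
  zero (noise-free inputs) or when the kept set approaches the model's
  degrees of freedom.
- Registration rotations are parameterized about the fixed-volume centre;
  optimizer scaling treats 0.02 rad comparable to 2 mm. Non-convergence
  raises a condition carrying the best transform so far.
- The difference map excludes out-of-image neighbours from the local mean
  rather than padding, so edge voxels are exact.

## Known limitations

- Straight tubes only; real PVS curve and branch. Counting is unaffected
  (clusters are per-slice) but tortuosity-sensitive extensions would need
  a different truth model.
- Grades near bin edges are sensitive to single-cluster differences; at 5%
  noise the max-slice count is accurate to about one cluster, which can
  move a grade when the count sits exactly on a boundary.
- The enlargement criterion (3 clusters above 3 mm) is checked on
  in-plane extents; a PVS running obliquely can exceed 3 mm in 3D while
  staying thin per-slice.
- Basal-ganglia and hippocampal PVS, DTI-based glymphatic indices, and
  qualitative findings (gliosis, malformations, ventricular calipers) are
  out of scope.
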