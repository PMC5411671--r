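---
title: "Reconstructing 3-D prostate lesions from template mapping biopsies: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3-D prostate lesions from template mapping biopsies: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpm3d)
```

## The question and the data

Transperineal template prostate mapping (TPM) biopsy samples the whole gland
through a brachytherapy grid every 5 mm, with two stacked 20 mm needles
(apex and base) per grid hole. When every core is potted separately, reported
with the distance of each cancer focus from its India-ink-stained apical end,
and registered to its grid coordinate, the pathology becomes a spatial data
set: up to 13 × 13 × 40 one-millimetre sections of Gleason-scored tissue.

`tpm3d` rebuilds three-dimensional cancer lesions from such core-level
reports and asks a targeting question: does the coordinate where a
cranio-caudal needle would return the longest cancer core length (the
*volume hotspot*) also capture the lesion's highest Gleason grade (the
*grade hotspot*)? If the two hotspots are concordant, directing a single
biopsy needle to a lesion's largest dimension attributes the correct grade;
if not, the 3-D distance between them measures how far a grade-blind needle
would land from the most aggressive tissue.

Because core-level TPM data sets are not publicly deposited, the package
ships a first-class synthetic cohort generator with planted ground truth;
every stage of the pipeline is tested against geometry that is known by
construction.

## Pipeline

1. **Coarse map.** Each core's cancer segments are painted into a
   13 × 13 × 40 voxel grid (5 × 5 × 1 mm voxels). The z origin sits at the
   apical end of the apex needle; apex cores occupy z ∈ [0, 20) mm and base
   cores z ∈ [20, 40) mm, abutting without overlap. Two counting rules for
   discontinuous cancer within one core are supported and propagated through
   the whole analysis: the *separate* count drops intervening benign tissue
   (one segment per focus), the *cumulative* count spans first focus start to
   last focus end. The cumulative rule needs a Gleason score for the merged
   segment; the package recombines patterns by length (primary weighted 0.6,
   secondary 0.4 within each focus) and takes the most abundant pattern as
   primary, the highest other as secondary. Sub-millimetre boundaries paint a
   voxel when they cover at least half of it; clinical CCLs are integer
   millimetres, so this rarely matters.
2. **Lesion delineation.** Independent lesions are connected components of
   the cancer voxels under 26-connectivity, evaluated in index space on the
   anisotropic blocks (a corner contact joins). Grades are ignored for
   connectivity — heterogeneity is a per-lesion property assessed later.
   Lesion ids are assigned in ascending order of each component's minimal
   (x, y, z) voxel, so labelling is deterministic and record-order
   independent. Lesion volume is the block count × 0.025 ml, the volume of
   one 5 × 5 × 1 mm block — the quantisation visible in the study's volume
   quartiles.
3. **Fine reconstruction.** Per Gleason pattern p ∈ {3, 4, 5} an indicator
   field (1 where the voxel's pair contains p) plus a cancer-presence field
   are interpolated trilinearly from the coarse voxel centres to a 0.5 mm
   isotropic grid, then convolved with an isotropic Gaussian. The smoothing
   width σ is tuned per patient: the largest σ (bisection on [0, 5 mm]) such
   that re-sampling the smoothed fields at the template grid sites still
   reproduces the original histology — cancer/benign status at every sampled
   site, and at cancer sites a voxel label equal to the site's highest
   Gleason pattern. σ = 0 always satisfies the constraint, so the search is
   well defined.
4. **Virtual needles.** For every 0.5 mm column of the sampling plane and
   every lesion, a virtual needle records the cancer length along the track
   (voxel count × 0.5 mm), the highest pattern on the track, the z midpoint
   of the cancer run and the z centroid of the highest-grade voxels. The
   volume hotspot set collects all columns attaining the lesion's maximal
   CCL; the grade hotspot set all columns whose track contains the lesion's
   maximal grade.
5. **Concordance.** Hotspots are concordant when the two column sets
   intersect (a set-membership question: some maximal-CCL needle captures the
   maximal grade). For discordant lesions the 3-D distance between the two
   hotspots is reported. Heterogeneity is classified from the set of Gleason
   pairs painted on the lesion's coarse voxels, under two criteria: *grades*
   (any two distinct pairs differ, so 3+4 next to 4+3 is heterogeneous) and
   *score* (pairs with equal totals are identified, so 3+4 with 4+3 is
   homogeneous). Homogeneous lesions are inherently concordant — their only
   grade is on every track.
6. **Cohort summary.** Per configuration ({separate, cumulative} ×
   {grades, score}) the summary reports lesion counts by score, volume
   median/IQR/range, homogeneous/heterogeneous counts, concordant and
   discordant heterogeneous lesions, discordant distances, and total
   concordance, each count with a Wald 95% interval
   (p ± 1.96·√(p(1−p)/n), percentage rounded to integer, half-width to one
   decimal). Wald is the unique standard interval that reproduces the
   published worked-example cells from their printed numerators and
   denominators. Quantiles use linear interpolation between order statistics
   (`stats::quantile` type 7).

## Key parameters

| parameter | default | meaning |
|---|---|---|
| grid pitch | 5 mm | lateral template spacing; fixes the coarse voxel |
| needle length | 20 mm | one depth slot; two slots span 40 mm |
| fine resolution | 0.5 mm | isotropic reconstruction voxel |
| `sigma_max` | 5 mm | upper bound of the σ search (one grid pitch) |
| `tol` | 0.02 mm | bisection tolerance for σ |
| `distance_method` | `"centroid"` | hotspot distance convention (see below) |
| `resample` | `"point"` | grid-site resampling operator (see below) |

In practice the tuned σ lands well below a millimetre (typically
0.6–1.0 mm): the 1 mm z sections are the binding constraint, because the
presence field of a cancer run must stay ≥ 0.5 at the run's last 1 mm
section and < 0.5 at the next benign one.

## Numerical and definitional choices

**Indicator semantics and the voxel label.** A pathology pair such as 3+4 is
read as sub-voxel intermixture of patterns 3 and 4, so the pattern fields
carry *contains* semantics and are interpolated and smoothed independently.
The fine voxel label is the *highest* pattern whose field is ≥ 0.5 at the
voxel (falling back to the largest field, ties towards the higher grade),
and the preservation check compares that label with the coarse voxel's
highest pattern. An alternative — label by the largest field ("most
abundant") — degenerates: inside a Gleason-3-bearing lesion the pattern-3
field is 1 almost everywhere, so any positive smoothing would erase every
high-grade label and force σ to 0. The highest-pattern rule keeps tuning
meaningful and matches what the grade hotspot must find: the highest grade
present. A strict mode additionally requires the full pattern *set* at each
site to be preserved.

**Resampling operator.** "Re-sampled at the template grid sites" is
operationalised as point evaluation at the coarse voxel centres (trilinear
from the fine voxel centres) — deterministic and exact for the
node-interpolation property. Block averaging over each 5 × 5 × 1 mm block is
available behind `resample = "block"` for sensitivity checks; note that
block averaging of the unsmoothed interpolant already fails at isolated
voxels, so it cannot anchor the σ search.

**Interpolation support.** Between the outermost voxel centres and the edge
of the coarse volume (half a voxel) fields are clamped to the boundary
value; beyond the volume they are zero. Pure zero extrapolation would make
grid-site preservation unattainable for lesions touching the field boundary
(the resampled presence at a boundary site would drop to 0.375 before any
smoothing). Convolution uses zero padding with a unit-mass kernel truncated
at 4σ: mass is conserved in the interior and decays across the volume
boundary.

**Hotspot distance.** The two hotspot *sets* decide concordance by
intersection. For discordant lesions the default distance is between the two
sets' centroids — volume points carry their cancer-run midpoint as z, grade
points their max-grade centroid. The centroid convention recovers the
planted focus offset in synthetic lesions; the alternative
`distance_method = "nearest"` (minimal pairwise distance) systematically
underestimates it by the radii of the two sets (roughly 2–4 mm at this
geometry) and is provided as the conservative lower-bound reading.

**Ties and degenerate inputs.** Connectivity ids order by minimal voxel;
grade ties break towards the higher pattern everywhere (conservative for
grade attribution); voxels claimed by two segments take the higher score; an
all-benign patient yields zero lesions and flows through to an empty
summary; tertiary patterns are parsed and stored but enter neither risk
classification nor the hotspot search by default.

**Performance.** Reconstruction runs on a crop of the coarse map (the cancer
bounding box plus one benign template site laterally and 3 mm in z). The
trilinear interpolant is identical inside the crop; the Gaussian tails that
the crop truncates lie where the fields are already essentially zero. This
keeps a typical patient under a second instead of allocating the full
65 × 65 × 40 mm field per smoothing iteration.

## What the synthetic generator emulates — and what it does not

Lesions are axis-aligned ellipsoids of a uniform base score; a
heterogeneous lesion carries one spherical high-grade focus. Default
conditions: 94 patients; Poisson(2.1) lesions per prostate (so some
prostates are benign); ellipsoid volumes lognormal (median 0.025 ml, long
upper tail, truncated to [0.01, 6] ml) with mild cranio-caudal anisotropy;
bulk scores 3+3 (61%), 3+4 (30%), 4+3 (5%), 4+4 (4%); 24% of lesions
heterogeneous; a planted focus sits at the lesion centre with probability
0.75, otherwise 5–15 mm towards the periphery; 10% of cancer-bearing cores
report their longest run as two foci around a 1–3 mm benign gap, exercising
the separate-vs-cumulative machinery. Sampling itself is deterministic and
exact: needle tracks are evaluated analytically against the ellipsoid
geometry at 0.5 mm steps, and each contiguous run is graded by
length-weighted pattern recombination — one pair per reported focus, as a
pathologist reports.

Three deliberate idealisation choices matter when reading test results:

* **Lesion centres and foci sit on template sites.** A 2 mm focus dropped
  between grid holes is never sampled, and grade heterogeneity confined to a
  single core is invisible across cores. So lesion centres snap laterally to
  the nearest grid site, planted foci snap to a sampled site, and
  heterogeneous lesions are drawn large enough to span at least two template
  columns. This makes the planted heterogeneity fraction recoverable
  downstream — a property of the generator, not of real prostates, where
  sub-sampling loss is real and unquantifiable without reference pathology.
* **Ellipsoid geometry.** Real lesions are irregular; geometry enters the
  pipeline only through its 5 mm grid samples, so simple shapes with
  controllable hotspot offsets are the right trade-off for testing, but
  passing tests say nothing about reconstruction error on irregular
  margins.
* **No clinical covariates, no imaging.** PSA, age, zonal anatomy and any
  MRI correlation are out of scope.

The hotspot-recovery study (`make_offset_cohort`) plants one large 3+3
lesion per prostate with a 2 mm Gleason 4+4 focus at offsets of 0, 5, 10 or
15 mm from the centre, on-axis and grid-aligned, with semi-axes grown with
the offset so the focus stays inside. Offset 0 must be classified
concordant, the rest discordant with the recovered 3-D distance within a
millimetre of the planted offset (median absolute error).

## Problem sizes used by the test-suite

The suites run entirely on synthetic data generated at test time: the
connectivity oracle compares 1000 random 10 × 10 × 10 maps against a
boolean transitive-closure partition; grid-site preservation is verified on
a 20-patient default cohort under both counting rules; hotspot recovery uses
50 lesions per planted offset (200 prostates); the remaining suites use
cohorts of 2–40 patients and hand-built maps. These sizes were chosen so the
whole suite exercises every stage at cohort scale while staying comfortable
to run locally.

## Known limitations

* Cores are assumed exactly on their nominal grid coordinates; needle
  deflection, registration error and tissue deformation are not modelled.
* The separate-count CCL of a core is taken as the *sum* of its foci; the
  longest single focus is exposed separately (`mccl_basis`) so the
  alternative reading remains computable.
* Preservation validates the highest pattern (optionally the pattern set),
  not the ordered pair: primary/secondary ordering below a site's highest
  pattern is not guaranteed to survive smoothing.
* Reconstructed CCLs are biased slightly downward for sub-centimetre lesions
  (thresholding a smoothed field shrinks small supports); hotspot
  *locations*, which drive the concordance question, are unaffected by this
  radial shrinkage in the tested geometries.
* With only ~10–50 heterogeneous lesions in a default cohort, discordance
  proportions carry wide binomial intervals — exactly why the summary prints
  them.
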