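# tpm3d — 3-D lesion reconstruction and hotspot concordance for TPM biopsy pathology

Transperineal template prostate mapping (TPM) biopsy samples the prostate
through a brachytherapy grid every 5 mm, two stacked 20 mm needles (apex and
base) per grid hole. When each core is potted separately, orientated by
India ink, and reported with the position and Gleason grades of every cancer
focus, the pathology amounts to a sparse 3-D image of the gland:
13 × 13 × 40 one-millimetre sections of Gleason-scored tissue.

`tpm3d` turns such core-level reports into 3-D cancer lesions and asks
whether image-targeted biopsy aimed at a lesion's largest dimension would
grade it correctly:

* the **volume hotspot** of a lesion is the sampling-plane coordinate where
  a cranio-caudal needle returns the longest cancer core length (CCL);
* the **Gleason grade hotspot** is the coordinate where a needle captures
  the lesion's highest Gleason grade;
* the two are **concordant** when the hotspot coordinate sets intersect —
  one needle at the maximum-CCL coordinate then also attributes the correct
  grade. For discordant lesions the 3-D distance between hotspots is
  reported.

## Method

For each patient and CCL counting rule (*separate*: benign gaps excluded;
*cumulative*: first focus start to last focus end), core segments are
painted into the 13 × 13 × 40 coarse map (5 × 5 × 1 mm voxels, apical end
of the apex needle at z = 0). Independent lesions are 26-connected
components of the cancer voxels; lesion volume is the block count × 0.025 ml.
Per Gleason pattern an indicator field is interpolated trilinearly to a
0.5 mm isotropic grid and convolved with an isotropic Gaussian whose single
width σ is tuned per patient to the largest value that still reproduces the
original histology when the smoothed map is re-sampled at the template grid
sites (cancer status and highest pattern at every sampled site). Virtual
needles on the 0.5 mm sampling plane then locate both hotspot sets per
lesion. Cohort summaries report counts with Wald 95% intervals,
p ± 1.96·√(p(1−p)/n), under four configurations: {separate, cumulative} CCL
× heterogeneity by {grades, score} (under the *score* criterion 3+4 and 4+3
count as one class).

Since core-level TPM data are not publicly deposited, the package includes a
synthetic cohort generator (`make_cohort`, `make_offset_cohort`) that plants
ellipsoidal lesions — optionally with a high-grade focus at a controlled
offset — and samples them through the exact template geometry, so hotspot
recovery can be scored against known ground truth. See the methods vignette
(`vignettes/tpm3d-methods.Rmd`) for the model, parameter defaults and design
choices.

## Worked example

One synthetic prostate with a large Gleason 3+3 lesion and a 2 mm Gleason
4+4 focus planted 10 mm from the lesion centre:

```r
library(tpm3d)
coh <- make_offset_cohort(offsets = 10, n_per_offset = 1, seed = 7)
rep <- analyze_cohort(coh, ccl_modes = "separate")
rep[, c("volume_ml", "score", "max_grade", "het_grades",
        "concordant", "distance_mm", "sigma")]
#>   volume_ml score max_grade het_grades concordant distance_mm     sigma
#> 1         3    34         4       TRUE      FALSE    10.11187 0.8984375
```

The lesion is heterogeneous (3+3 bulk with 3+4 cores where the focus was
sampled), its hotspots are discordant, and the recovered 3-D hotspot
distance (10.1 mm) matches the planted 10 mm offset; the tuned smoothing
width was 0.90 mm. A cohort-level summary for one configuration:

```r
coh <- make_cohort(cohort_spec(n_patients = 8, seed = 42))
reports <- analyze_cohort(coh)
summarize_cohort(reports, analysis_config("separate", "grades"))
#> Analysis configuration: separate count / Gleason grades
#>   independent lesions: 15
#>   Gleason 3+3: 7 (47±25.2%)
#>   Gleason 3+4: 5 (33±23.9%)
#>   Gleason 4+3: 2 (13±17.2%)
#>   Gleason 4+4: 1 (7±12.6%)
#>   lesion volume ml: median 0.150 (IQR 0.125-0.188, range 0.100-0.525)
#>   homogeneous: 13 (87±17.2%) | heterogeneous: 2 (13±17.2%)
#>   heterogeneous concordant: 2 (100±0.0%) | discordant: 0 (0±0.0%)
#>   total concordant: 15 (100±0.0%)
```

Count cells print as `k (p±hw%)`; `binomial_wald_ci(148, 195)$label`
returns `"148 (76±6.0%)"`.

## Analysis workflow

The numbered scripts under `analysis/` run the study end to end and write
their outputs under `results/`:

1. `01_simulate_cohort.R` — simulate the 94-patient cohort (per-patient core
   CSVs + ground-truth JSON);
2. `02_reconstruct_lesions.R` — rebuild maps under both counting rules, tune
   σ, locate hotspots (`results/lesion_reports.csv`, `results/sigma_log.csv`);
3. `03_summarize_configurations.R` — the four-configuration summary table;
4. `04_hotspot_recovery.R` — recovery of planted focus offsets
   (0/5/10/15 mm) with a figure;
5. `05_visual_maps.R` — colour-coded per-patient visual reports (red/yellow/
   green/white risk classes, CCL per cell) as PNG + JSON.

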