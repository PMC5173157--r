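# ctvqa

Quality-assurance metrics and decision logic for validating atlas-based
auto-segmentation of rectal clinical target volumes (CTVs) against expert
reference contours.

Radiotherapy departments that run a two-step delineation QA workflow — a
first operator contours, a second expert performs an independent check (IC)
— can replace the first operator with auto-contouring software only if the
geometry is close enough to expert work *and* real time is saved. `ctvqa`
implements the full validation arithmetic for that question, plus a seeded
synthetic cohort generator that emulates expert and auto-segmented contour
sets, so the whole pipeline is testable without clinical data.

## What it computes

For a reference delineation A (the agreed "master contour") and a test
delineation B, both stacks of closed planar polygons in millimetres:

* **Volumetric Dice similarity coefficient** —
  DSC = 2|A∩B| / (|A| + |B|), with per-slice exact polygon areas and
  intersections weighted by slice thickness. 1 = total overlap, 0 = none.
* **Mean slicewise Hausdorff distance (MSHD)** — the symmetric Hausdorff
  distance computed per axial slice between the two boundaries, averaged
  over reference slices with a test counterpart; unmatched slices are
  counted and reported.
* **Cohort summaries** — MDSC (median of per-patient DSC) ± 1 SD and mean
  MSHD ± 1 SD, with an outlier-sensitivity re-summary that removes the k
  worst patients by combined DSC/MSHD rank.
* **Time analysis** — per patient T1 (first operation), T2 (independent
  check), TT = T1 + T2; group means ± SD; total-time saving by both the
  ratio-of-means and the per-patient estimator; paired Student's t-test on
  TT differences; unpaired IC-time comparison across slice-thickness
  subgroups.
* **Acceptance decision** — inclusive thresholds (defaults MDSC ≥ 0.75,
  MSHD ≤ 1 mm, TT saving ≥ 50%); accept iff ≥ 2 of 3 criteria hold and the
  time-saving criterion is among them.
* **Atlas ranking** — Gower-style mixed distance over clinical and
  anthropometric selection parameters (stage, tumor localization, sex, age,
  weight, height, BMI, fertility state, sacro-coccygeal and inter-iliac
  distances).

Contours are exchanged as a simple JSON format or read from DICOM
RT-STRUCT; metric tables and the QA report are written as CSV, JSON
(schema-validated) and markdown.

## Worked example

```r
library(ctvqa)

# a synthetic reference CTV and an "auto-segmented" counterpart
ref  <- generate_reference(shape_params(n_slices = 8, slice_thickness_mm = 5),
                           seed = 42, patient_id = "P001")
auto <- perturb(ref, perturb_model(radial_bias_mm = 1, radial_sigma_mm = 2),
                seed = 7)
compare_delineations(ref, auto)
#> <overlap_result> P001: DSC 0.9089, MSHD 3.296 mm (8/8 slices matched)

# the decision engine on an observed cohort triple
evaluate_acceptance(mdsc = 0.75, mshd_mean_mm = 2.00, tt_saving_pct = 55.5)
#> <qa_decision> MDSC 0.750 [met]  MSHD 2.00 mm [not met]  TT saving 55.5% [met]
#>   2/3 met, mandatory met -> ACCEPTED
```

A 1 mm systematic bias with 2 mm correlated boundary noise costs ~0.09 of
Dice but over 3 mm of MSHD — boundary-distance metrics punish local
deviations that area metrics forgive, which is exactly why the decision
rule keeps both. The observed triple in the second call meets the Dice
criterion on its boundary (comparisons are inclusive) and the mandatory
time criterion, so the system is accepted with 2 of 3 criteria met.

## The analysis workflow

The `analysis/` scripts run the study end to end on the default synthetic
cohort (44 patients: 14 atlas + 30 test; 29 at 5 mm, 15 at 2.5 mm slice
thickness), writing tables to `results/` (the bulky contour dataset goes to
`scratch/`, regenerable from config + seed):

```sh
Rscript analysis/01_simulate.R          # cohort, profiles, timings, provenance
Rscript analysis/02_overlap_metrics.R   # per-patient DSC/MSHD + cohort summary
Rscript analysis/03_time_and_decision.R # time analysis, t-tests, QA report
Rscript analysis/04_atlas_matching.R    # atlas-library ranking per test patient
```

Step 3 also evaluates a cohort tuned near the DSC acceptance boundary; it
prints `MDSC 0.753, MSHD 7.18 mm, TT saving 55.0% -> 2/3 met, ACCEPTED`,
the characteristic pattern of an auto-contourer that is accepted on Dice
plus time saving while failing the Hausdorff criterion.

The methods vignette (`vignettes/delineation-qa.Rmd`) documents the model
assumptions, parameter defaults, numerical tolerances and the limits of
what synthetic cohorts can demonstrate.

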