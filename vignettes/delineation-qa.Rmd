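---
title: "Validating auto-delineation against expert contours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating auto-delineation against expert contours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical target volume (CTV) delineation for rectal-cancer radiotherapy is a
major source of systematic error: disagreement between trained observers can
reach a centimetre, concentrated in the upper-anterior and inferior
mesorectum. Departments that run a two-step quality-assurance (QA) workflow —
a first operator contours, a second expert performs an independent check
(IC) — pay for that safety in planning time. Atlas-based auto-segmentation
promises to replace the first operator: a library ("atlas") patient whose
anatomy best matches the new scan is selected, and its contours are
propagated. Whether that replacement is clinically acceptable is an
empirical question with three ingredients: geometric agreement with a
reference contour, sensitivity to local failure, and actual time saved.

`ctvqa` implements that validation as a reusable pipeline: overlap metrics,
timing analysis, a multi-criterion decision engine, atlas-candidate ranking,
and a synthetic cohort generator that stands in for clinical delineations
(which are rarely shareable).

## Data model

A delineation is a stack of closed planar polygons in patient-space
millimetres, one or more per axial slice, with slice-thickness metadata
(`structure_delineation`). Polygons are cleaned on ingest: consecutive
duplicates removed (1e-9 mm), orientation normalised counter-clockwise,
self-intersecting or zero-area input refused. Multiple polygons on a slice
are treated as a union region; holes are not modelled because rectal CTV
cross-sections are simply connected in practice. Slices of two delineations
are matched by z with a 0.01 mm snap — both derive from the same planning CT
grid, so fuzzier matching is unnecessary. The canonical exchange format is a
small JSON document; DICOM RT-STRUCT structure sets (explicit VR little
endian) can be ingested directly.

## Overlap metrics

**Dice similarity coefficient (DSC).** `patient_dsc()` computes
2|A∩B| / (|A| + |B|) volumetrically: per-slice areas and intersections are
multiplied by slice thickness and summed, and slices present in only one
delineation count only in the denominator. 0 means no overlap, 1 total
overlap. Areas and intersections are *exact* polygon quantities — shoelace
areas plus a Green's-theorem boundary integral over the pieces of each
boundary inside the other region, with half weight for coincident boundary
arcs. Rasterisation appears only as an independent cross-check oracle in the
test suite, so pixel resolution is never a hidden parameter of the metric.

**Slicewise symmetric Hausdorff distance and MSHD.**
`slice_symmetric_hausdorff()` is 2D within-slice, per the slicewise
construction used in delineation QA: the maximum over both directed
Hausdorff distances between the two boundaries. Boundaries are resampled at
a 0.1 mm arc-length step and measured against the other side's exact
segments, which bounds the sampling error by step/2 = 0.05 mm — far below
the 1 mm acceptance threshold — and keeps the result independent of vertex
density. `patient_mshd()` averages the per-slice distances over reference
slices that have a test counterpart. Reference slices with no test contour
(e.g. cranio-caudal truncation by the auto-contourer) are always counted
and reported; by default they are excluded from the mean, because a
Hausdorff distance against an empty set is undefined and a silent penalty
would distort comparability. An explicit `"penalise"` policy is available
(distance = slice thickness × slices to the nearest test slice) for users
who prefer truncation to hurt the score.

**Cohort aggregation.** The cohort statistic is the median of per-patient
DSC (MDSC) with its sample SD, and the mean of per-patient MSHD with its
sample SD. Two aggregation choices were genuinely open and are fixed here
as: DSC is volumetric per patient first, then the median is taken across
patients (an alternative reading — median across slices — would weight
slices, not patients); and SDs use the n−1 denominator throughout. Medians
use the midpoint convention for even n.

## Time analysis and the decision rule

Each patient contributes T1 (first operation: manual contouring, or atlas
choice + propagation), T2 (independent check) and TT = T1 + T2, in minutes.
Two total-time-saving estimators are always reported, because they answer
different questions and can disagree materially when times vary across
patients:

* ratio of means: 100·(mean TT_A − mean TT_B)/mean TT_A — the saving on the
  workload of the whole programme (the default for the decision);
* mean of per-patient ratios: the saving the typical patient experiences.

Per-patient TT differences are tested with the classical paired Student's
t-test (n−1 df, two-sided, 95% CI). The IC-time comparison across
slice-thickness subgroups uses an unpaired pooled-variance t-test, since
different patients were scanned at each thickness.

The decision engine evaluates three criteria with *inclusive* comparisons —
MDSC ≥ 0.75, MSHD ≤ 1 mm, TT saving ≥ 50% by default — and accepts when at
least two hold **and** the time-saving criterion is among them. The
mandatory-time rule reflects the purpose of the system: a contouring aid
that saves no time fails its reason for existence regardless of geometry.
Inclusivity matters in practice because observed MDSC values sit exactly on
the 0.75 boundary in published validations; the engine treats the boundary
as met, and a property test verifies the decision is monotone (improving
any observed value never revokes acceptance).

**Outlier sensitivity.** Validation cohorts contain "irregular anatomy"
patients (bowel loops filling the pelvis, a large uterine fibroma) on which
atlas propagation fails qualitatively. The sensitivity analysis removes the
k worst patients under a reproducible combined rank — rank by ascending DSC
plus rank by descending MSHD, ties broken by patient id — and re-summarises.
The combined rank is this package's construction; qualitative outlier
identification is not reproducible, a rank rule is.

## Atlas ranking

`rank_atlas()` scores library patients against a test patient with a
Gower-style mixed distance over the selection parameters used in clinical
atlas workflows: stage (ordinal, scaled rank difference), tumor
localization, sex and fertility state (0/1 mismatch), and age, weight,
height, BMI, sacro-coccygeal and inter-iliac distances (absolute difference
over the cohort range). Missing fields are skipped with weight
renormalisation; weights default to uniform because no published weighting
exists. The result is in [0, 1], symmetric, and deterministically ordered
(ties by patient id). Contour propagation itself is a proprietary black box
and is out of scope; only the selection step is modelled.

## The synthetic cohort generator

The generator produces the study's full input set as a pure function of a
configuration and a master seed: every artifact is byte-reproducible.

**Reference shapes.** One star-shaped polygon per slice,
r(θ, z) = R(z)·(1 + Σₖ aₖ cos(kθ + φₖ)), sampled at 180 vertices, with a
quadratically tapered axial radius profile, low-order Fourier boundary
irregularity (defaults a = 0.05, 0.03, 0.015 on harmonics 2–4) and a smooth
in-slice centre drift. Defaults (base radius 25 mm, axial extent 100 mm)
give CTV-scale volumes of a few hundred cm³. Star-shape guarantees simple
polygons whenever all radii stay positive.

**Perturbation.** Observer and algorithm disagreement is modelled as a
radial displacement field: a systematic bias plus a zero-mean Gaussian
field that is *smooth*, not white — spectral synthesis on the boundary
angle with harmonic variances decaying as (1 − angular_corr)^k, carried
across slices by an AR(1) process with coefficient axial_corr. Smooth
disagreement is what inter-observer studies describe; white jitter would
inflate Hausdorff distances without moving area overlap. The pointwise SD
of the field equals radial_sigma exactly by construction. Defaults: group A
(expert manual) bias 0.5 mm, σ 1.0 mm; group B (automatic) bias 1.0 mm, σ
2.0 mm with a 20% chance of losing up to two caudal slices. Outlier
anatomies add a localized outward bump (default 25 mm amplitude, 0.9 rad
angular width, 45 mm axial span — the scale of a large pelvic mass); the
span is specified in millimetres so the emulated anatomy is the same
physical size in the 5 mm and 2.5 mm thickness subgroups.

**Timing.** Delineation times are positive and right-skewed (reported SDs
approach their means), so each group/column is lognormal with parameters
solved analytically from the target mean and SD (defaults: manual T1
13.12 ± 4.84, manual T2 10.20 ± 5.15, auto T1 1.12 ± 0.44, auto T2
9.72 ± 8.67 minutes). Thin-slice (2.5 mm) patients get an additive T2 shift
(default +2 min): twice the slices take longer to review. Real per-patient
delineation-time distributions are unpublished; moment-matched lognormals
are an assumption and are flagged as such.

**Cohort layout.** 44 profiles — the first 14 atlas, the remaining 30 test;
the first 29 at 5 mm slice thickness, the last 15 at 2.5 mm — with
anthropometrics drawn from plausible adult ranges (they only feed atlas
ranking, so realism requirements are weak). Each test patient gets a
reference plus one group-A and one group-B perturbation; sub-seeds all
derive from the master seed.

**What passing tests do and do not show.** The generator reproduces the
*statistical structure* the analysis assumes — graded, spatially smooth
boundary disagreement; thickness subgroups; labelled outliers; skewed
timing — not real pelvic anatomy, not CT intensities, and not the error
modes of any particular registration algorithm. Tests passing on synthetic
cohorts validate the metrics, bookkeeping and decision logic; they say
nothing about how any commercial auto-contourer performs on patients.
Correspondingly, cohort-level geometric results at clinical scale (e.g. an
MDSC of 0.75 simultaneous with an MSHD of 2 mm) are not reproducible from
this generator: with a smooth displacement field at 25 mm structure radius,
an MSHD of 2 mm implies a far higher Dice than 0.75, because area metrics
forgive what boundary-distance metrics punish. The package therefore
validates the *rules* on such observed triples directly, and the analysis
scripts demonstrate the decision pattern (accept on DSC + time saving with
the MSHD criterion failed) on a cohort tuned near the DSC boundary.

## Numerical choices

* Exact polygon booleans, tolerance 1e-9 mm for on-boundary classification;
  coincident arcs get half weight from each side, so identical regions
  intersect at full area and externally touching regions at zero.
* Hausdorff resampling step 0.1 mm (error ≤ 0.05 mm); the brute-force test
  oracle samples at 0.02 mm.
* Slice matching tolerance 0.01 mm; slice grids validated to 1e-6 mm.
* Degenerate cohorts (n = 1) report SD = 0 with an explicit
  `sd_defined = FALSE` flag rather than NA, so reports stay printable.
* Zero-variance differences refuse the paired t-test rather than returning
  an infinite statistic.
* All ranking tie-breaks (atlas candidates, outlier removal) are by patient
  id, making every ordering deterministic.

## Problem sizes in the test suite

The property suites run at sizes chosen to exercise the asymptotics while
staying comfortably interactive: 200 random polygon pairs for the
Hausdorff-vs-oracle bound; cohorts of 20 patients × 6 slices across noise
levels σ ∈ {0.5, 1, 2, 4} mm over 20 replicate seeds for the monotonicity
property; 10-patient cohorts for bias recovery at b ∈ {0.5, 1, 2} mm; and
10,000 draws for timing moment checks. The full 44-patient study
configuration is exercised once per analysis script run.

## Known limitations

* Holes and multi-label structures are not modelled; organs at risk are out
  of scope.
* The 2D slicewise Hausdorff ignores 3D cranio-caudal surface distance; a
  truncated contour stack shows up in the unmatched-slice count, not in the
  distance itself (unless the penalise policy is chosen).
* Atlas ranking models selection only; no claim is made about propagation
  quality, and increasing library size is not studied.
* The RT-STRUCT reader supports explicit VR little endian only, which
  covers structure sets exported by major planning systems but not implicit
  VR archives.
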