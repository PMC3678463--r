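---
title: "Quantitative depth-profile analysis of subchondral bone ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative depth-profile analysis of subchondral bone ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qusbone)
```

## The measurement problem

Osteoarthritis densifies (scleroses) the subchondral bone just beneath the
articular cartilage. Because acoustic impedance rises with density, a
sclerotic cartilage–bone interface reflects more ultrasound: on a B-mode
image of the femur the interface brightens and, as its integrity degrades,
the reflection spreads from a sharp line into a band, flattening the decay
of echo intensity with depth. `qusbone` turns these qualitative signs into
numbers: a normalized depth–intensity profile of the subchondral bone at
three femoral sites (medial condyle `MED`, intercondylar sulcus `SULC`,
lateral condyle `LAT`), summarised into five depth-level means, an overall
mean, and an intensity slope, and compared against ordinal clinical gradings
(radiographic Kellgren–Lawrence, arthroscopic Noyes).

## The profile chain

Starting from an operator-placed border line on the cartilage–bone interface
(placed where the beam is perpendicular to the bone, so the specular
reflection is strongest), the chain runs in a fixed order:

1. **ROI selection** (`selectROI`). A rectangle 2 mm wide, centered
   laterally on the annotation's center column, extending 8 mm downward
   from 3 px above the annotated interface row. Pixel counts derive from
   the pixel pitch alone — 29 × 114 px at the 31 mm imaging-depth raster,
   22 × 88 px at 41 mm — never from image content. Conversions round half
   away from zero, which reproduces both of those widths.
2. **Row means** (`computeProfile`). The profile is the arithmetic mean
   gray level of each horizontal ROI row, shallow to deep.
3. **Normalize and cut** (`normalizeAndCut`). Dividing by the global
   maximum removes overall gain differences between acquisitions; cutting
   the vector to start at that maximum anchors depth 0 on the interface
   reflection. A tie at the maximum keeps the first (shallowest)
   occurrence, preserving the deepest usable extent.
4. **Resample** (`resampleProfile`). Linear interpolation onto the 31 mm
   reference pitch (0.07 mm) makes the two depth settings comparable. The
   output grid shares the input's origin, so the leading 1 is preserved
   exactly, and no extrapolation occurs beyond the last native sample.
5. **Truncate** (`truncateProfile`) to 25 samples (~1.74 mm of bone).
6. **Summaries** (`profileLevelMeans`, `profileSlope`). Five uniform
   5-sample levels (level 2 spans 0.35–0.70 mm, the depth found most
   responsive to sclerosis); the slope is the ordinary least-squares line
   over the first 10 samples (~0.7 mm), in normalized intensity per mm.
7. **Femoral average** (`femoralAverage`). Every field is averaged
   arithmetically over the sites available for a subject (label `FB`);
   missing sites are omitted and the contributing count recorded.

### Numerical choices

- *Guard margin.* The ROI starts 3 px above the annotated row only so that
  the reflection maximum falls inside it; since the profile is subsequently
  cut at its maximum, the exact top placement is immaterial, and the guard
  is kept as a documented free parameter of `selectROI`.
- *Slope estimator.* OLS over the 10-sample window against physical depth
  in mm, rather than a two-point difference: robust to single-sample noise
  and interpretable in physical units. Computing against pixel index
  instead would change the slope by a constant factor only; all ordinal
  statistics are invariant to that choice.
- *Reference pitch.* 0.07 mm, configurable (`referencePitchMm`); 25 samples
  at this pitch give the nominal 1.74–1.75 mm analysis depth.
- *Degenerate inputs.* An all-zero profile refuses to normalize; a
  post-resampling profile shorter than 25 samples raises a per-site error,
  the site is dropped and logged, and the femoral average proceeds over the
  remaining sites — mirroring the per-site attrition real cohorts show.

## Statistics

Grading constructs: the seven-step Noyes scale maps to 0–6
(`convertNoyes`); FAS1 (`fas1Score`) is the sum of the three site grades
(0–18); FAS2 (`fas2Score`) bins FAS1 as 0; 1–6; 7–12; 13–18 into grades
0–3 to form groups large enough for t comparisons.

`spearmanCorrelation` uses midranks for ties (mandatory with few-level
ordinal gradings) on pairwise-complete observations — missing K-L grades
or missing site images simply reduce the per-comparison n, without
imputation. The p-value uses the t approximation on n − 2 degrees of
freedom, the default of mainstream statistical software for tied data; an
exact permutation option is available for n ≤ 8, where full enumeration
(≤ 40 320 permutations) is cheap. Confidence intervals come from the
Fisher r-to-Z construction (`fisherCI`): symmetric about atanh(r) with
half-width `qnorm(0.975)/sqrt(n - 3)` — the full-precision quantile
1.959964 rather than 1.96, though the printed 3-decimal bounds reproduce
with either. Group comparisons (`twoSampleT`) default to the classical
pooled-variance Student's t, with Welch behind a flag, since pooled-vs-Welch
is ambiguous in most clinical reports; both are exposed.
`correlationTable` renders variable × grading grids with significance stars
(\*, \*\*, \*\*\* at 0.05, 0.01, 0.001) and applies no multiple-testing
correction — each row is a marginal test, and the run log says so.

## What the synthetic generator emulates — and what it does not

No clinical images ship with the package; `simulateImage`/`writeCohort`
generate a phantom cohort whose geometry and severity signal reproduce the
*conditions* of the measurement, so every downstream stage is testable.

A single latent severity s in [0, 1] drives three monotone links, the
directions of which encode the physics (brighter interface, flatter decay,
line-to-band spreading with sclerosis); the coefficients are the
generator's calibration, chosen once as plausible mid-range values:

- interface peak reflectivity: `0.5 + 0.5 s` (fraction of full scale),
- sub-interface exponential decay: `2.0 − 1.2 s` per mm,
- interface band half-width: `0.1 + 0.2 s` mm.

Each column's intensity is the analytic `phantomIntensity` model — a
cartilage baseline (0.05) above, a Gaussian band shoulder peaking exactly
on the interface, exponential decay below — multiplied by unit-mean gamma
speckle (shape 1/CV², CV 0.3 by default; gamma chosen for positivity, as
any positive unit-mean multiplicative model is equally defensible),
then quantized to 8 bits. The interface follows a gentle parabola
(condyles more bowed than the sulcus, 1e-3 vs 2.5e-4 px/px²; purely
cosmetic and configurable) whose apex is anchored to the raster row
nearest the nominal 15 mm apex depth, so the analytic profile is sampled
on the pixel grid. Default rasters are 443 × 380 at 31 mm depth (pitch
≈ 0.0700 mm) and 451 × 380 at 41 mm (≈ 0.0909 mm) — raster sizes are a
free inference from the published per-ROI pixel counts and remain
configurable.

Grades are linked to the same severity: K-L = clamp(round(4 s + e), 0, 4)
and per-site Noyes = clamp(round(6 s + e′), 0, 6), with Gaussian noise
sd 0.7 (K-L) and 1.0 (Noyes). Those scales keep the severity–grade rank
correlation strong (≈ 0.9 at n = 200) while producing the grade overlap a
real cohort shows. Cohort defaults emulate the study scale: 40 subjects,
severities uniform on [0, 1], imaging depth 31 or 41 mm per subject, a 5%
per-site image dropout and a 20% chance of a missing K-L grade
(matching the roughly four-fifths radiographed in practice).

What the phantom does **not** emulate: beam physics (focusing, refraction,
frequency-dependent attenuation), anatomy beyond one interface (cartilage
layering, osteophytes, the patellar acoustic shadow that limits the
lateral compartment), operator variability in probe angle, and any
intensity texture beyond i.i.d. speckle. Passing tests therefore show the
*pipeline* is correct and recovers a monotone severity signal under
realistic noise and missingness — not that the effect sizes on clinical
images will match. On synthetic cohorts the severity→grade and
severity→image links share one latent variable with no angle-of-incidence
error, so correlations run higher than the moderate values seen in vivo;
only their sign structure and the printed-value arithmetic (CI bounds,
scale maxima, geometry) are claimed.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run a 40-subject default
cohort (the study's scale) for parameter recovery, 20-seed repeats for
the automatic interface detector, and 500–1000 replicates for the
permutation-null and type-I-error checks of the statistical engine; these
sizes give the binomial 99% acceptance bands quoted in the tests.

## Known limitations

- Only single-frame grayscale PNG (plus CSV sidecar) I/O is built in;
  clinical DICOM exports should be converted upstream.
- The automatic interface finder (`autoInterface`) is a convenience for
  well-behaved images; the supported workflow is a manual annotation, as
  in clinical practice.
- No oblique ROIs: the ROI follows image axes, relying on the operator
  choosing a location where the interface is perpendicular to the beam.
- No multiple-testing correction in correlation tables (by design,
  flagged in the run log).
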