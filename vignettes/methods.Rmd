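---
title: "Point-to-point structure-function analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-to-point structure-function analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In early and intermediate (non-exudative) age-related macular degeneration,
drusen accumulate between the retinal pigment epithelium (RPE) and Bruch's
membrane, and hyperreflective foci (HRF) appear as small lesions on OCT.
Whether these lesions depress the light sensitivity of the *overlying*
photoreceptors — rather than merely marking diffuse disease — is a
point-to-point question: each microperimetry stimulus must be matched to
the OCT A-scans directly beneath it, and the local lesion load quantified
there.

`mpstruct` implements that pipeline end to end, replacing the clinical
cohort and proprietary device outputs with a seedable synthetic-data
generator so every stage is verifiable at desk scale:

1. **Grid geometry** (`mp_grid_default`, `deg_to_px`, `etdrs_sector`) — a
   45-point high-density stimulus pattern, degree/mm/pixel conversions on
   the anisotropic OCT raster, ETDRS subfield assignment.
2. **Registration** (`fit_affine`, `map_grid_to_oct`) — least-squares
   affine estimation from user-marked keypoint pairs linking the fundus
   photograph (CFP) of the microperimeter to the SLO/OCT frame.
3. **En-face quantification** (`drusen_thickness_map`, `roi_mask`,
   `roi_volume`, `hrf_roi_volume`) — per-A-scan drusen thickness
   (RPE-to-Bruch distance), circular regions of interest around each
   mapped stimulus, ROI volumes via the unit-pixel-area summation.
4. **Staircase psychophysics** (`staircase_421`, `simulate_exam`) — a
   4-2-1 adaptive threshold procedure bounded to the 0–34 dB range.
5. **Inference** (`fit_volume_model` and friends) — nested linear mixed
   models of sensitivity on local lesion volumes, visit and eccentricity.

## The generative and statistical model

Measured sensitivity at spot $s$ of eye $e$ in patient $p$ at visit $v$:

$$
S_{pesv} = \beta_0 + \beta_d V^d_{esv} + \beta_h V^h_{esv} + \beta_v v
  + \beta_{ecc}\,\mathrm{ecc}_s + \beta_{dv} V^d_{esv} v
  + \beta_{de} V^d_{esv}\,\mathrm{ecc}_s
  + u_p + u_{e(p)} + u_{s(e)} + \varepsilon_{pesv},
$$

clamped to the instrument range $[0, 34]$ dB, with nested Gaussian random
intercepts (patient, eye within patient, spot within eye) that are
constant across visits, and volumes $V^d, V^h$ in $10^{-3}\,$mm$^3$ units.
The synthetic generator *produces* data from this model (evaluating the
ROI volumes on its own fields at the ground-truth stimulus positions,
then passing the true threshold through the staircase); the fitting stage
*estimates* it by REML via `lme4`, with Wald z inference. This closed
loop is what the parameter-recovery tests exercise.

The volume-unit choice resolves a dimensional ambiguity in how such
estimates are reported in the clinical literature: with volumes in
$10^{-3}$ mm$^3$, the default effects $\beta_d = -0.991$ and
$\beta_h = -5.230$ are dB-scale, consistent with the printed volume
summaries (median per-spot drusen volume of order $10^{-2}$ to $1$ in
these units, HRF volumes of order $10^{-1}$).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mm_per_degree` | 0.30 | mm/deg | standard emmetropic scaling; makes the $20°\times20°$, $1024\times97$ raster's pixel area $(6/1024)(6/97) = 0.000362$ mm² |
| `roi_diameter_um` | 240 | µm | the ROI circle size; read as a *diameter* (radius 120 µm) — the source description does not say which, so this is configurable |
| `hrf_min_volume_mm3` | $6\times10^{-5}$ | mm³ | detectability floor: smaller ROI HRF volumes are set to 0 to exclude segmentation noise |
| `n_bumps_mean` | 12.7 | bumps/eye | Poisson mean of drusen bumps; calibrated so ~73.47% of baseline stimuli overlie drusen |
| `blob_rate` | 2.15 | blobs/eye | Poisson mean of HRF blobs; calibrated so ~2.02% of baseline stimuli carry post-floor HRF |
| `intercept_db` | 26.45 | dB | calibrated so baseline mean *measured* sensitivity is ~25.71 dB (it sits above that value because eccentricity/volume terms and the staircase's small negative bias pull the marginal mean down) |
| `sd_patient, sd_eye, sd_spot, sd_resid` | 1.5, 1.0, 1.5, 1.0 | dB | chosen so the total SD of baseline sensitivity is ~3.5 dB |
| `growth_rate_per_visit` | 1.05 / 1.08 | — | multiplicative quarterly growth of drusen / HRF volume |
| `keypoint_jitter_px` | 0.5 | px | marking error of the simulated user; with 5 keypoints the median stimulus mapping error stays below 1.5 px |
| staircase start | 17 | dB | mid-range start; steps 4→2→1 dB, terminate at the first reversal on the 1-dB step |

Calibration precision of the generator defaults (estimated over 24
replicate cohorts during development): about 0.5 coverage points for
drusen, 0.15 points for HRF, 0.05 dB for mean sensitivity. The test suite
allows for exactly this slack on top of Monte-Carlo error when it checks
that replicate cohorts bracket the targets.

## What the generator emulates — and what it does not

Emulated: foveally concentrated drusen as sums of isotropic (in physical
mm) Gaussian elevation bumps with a detection threshold of 0.5 µm;
sparse HRF as small Gaussian thickness blobs placed preferentially over
drusen; multiplicative lesion growth across up to 5 quarterly visits;
per-eye ground-truth CFP→SLO affines (rotation ≤ ±5°, per-axis scale
0.9–1.1, translation ≤ ±50 px, no reflections) with jittered keypoints;
a psychometric observer (cumulative Gaussian, spread 0.5 dB, 3% lapse
rates) behind the 4-2-1 staircase; the 35-patient / 51-eye / 5-visit
cohort shape with both eyes contributed by 16 patients.

Not emulated: 3D OCT signal (no speckle, no B-scan intensities, no layer
segmentation errors beyond the thickness-crossing clamp), drusen
regression/collapse, HRF migration depth, fixation instability, spatial
correlation between neighbouring spots beyond the spot intercept, and
conversion to advanced AMD. Passing tests therefore validate the
*pipeline arithmetic and the inference machinery* under a faithful but
idealized data-generating process — they do not certify segmentation
robustness on real scans.

## Numerical choices

- **ROI inclusion** is cell-centre-in-circle on the anisotropic grid
  (distances in mm), with no area weighting — this matches the A-scan
  summation formula used for volumes. Continuous (unrounded) centre
  coordinates are kept.
- **Bump evaluation** is truncated at 4σ (keeps >99.96% of the analytic
  Gaussian volume). The closed-form check (discrete sum vs
  $2\pi\sigma^2 A$) holds within 1% for σ ≥ 0.3°; below roughly 1.5× the
  B-scan spacing the 97-row sampling aliases the bump and the bound
  degrades — widths that coarse are outside the generator's default
  range.
- **Affine estimation** solves the 6-parameter least-squares problem by
  QR factorization (no iteration, no RANSAC: synthetic keypoints are
  clean; a 2 px RMS gate substitutes for the visual inspection a human
  operator would perform).
- **Staircase convention**: start 17 dB, seen → dimmer, shrink
  4→2→1 dB at reversals, stop after the first reversal at 1 dB or when
  pinned at a range boundary; threshold = highest level answered seen;
  an observer who never sees scores the 0 dB floor. Device-exact
  bookkeeping is proprietary, so this convention is isolated behind the
  `staircase_result` contract.
- **Degenerate inputs**: ROI centres outside the raster yield empty
  masks flagged rather than errors; constant presence indicators abort
  the presence model with an explicit non-identifiability message; empty
  ETDRS sectors are dropped with a warning and the Bonferroni factor is
  the number of pairs actually tested.
- **Ties**: ETDRS quadrant boundaries on the ±45° diagonals are assigned
  by half-open angular intervals, so diagonal points resolve
  deterministically.
- **Seeding** is counter-based (`derive_seed`): each eye, visit and
  purpose gets an independent derived stream, so enlarging a cohort does
  not reshuffle existing eyes.

## Design decisions taken where the design was open

- "45 stimuli in 8° around the fovea" is read as an 8°-*diameter* field:
  1 central spot plus rings of 4, 8, 8, 12, 12 at 0.5°–4°. The exact
  commercial layout is not published as coordinates; custom patterns load
  from CSV.
- Registration is estimated once per eye (baseline) and reused across
  follow-ups, mirroring device follow-up mode; the keypoints table keeps
  a visit column for schema stability.
- Inference uses Wald z (the reporting convention of the emulated
  analysis does not state its p-value method); REML for estimates and
  CIs, ML refits for AIC comparisons. Visit is coded 0–4 as an integer
  covariate.
- Presence is defined as volume > 0 for drusen and post-floor volume > 0
  for HRF, exactly.
- Clamped 0/34 dB sensitivities are kept as observed values; no censored
  -response model.

## Problem sizes used by the test suite

Unit tests run on reduced cohorts (2–10 patients, 1–3 visits) and on
tables simulated directly from the linear model where only the inference
stage is under test (e.g. 200 replicates of 10 patients × 2 visits for
the type-I-rate check). The acceptance-grade checks simulate five
full-size cohorts (35 patients, 51 eyes, 45 spots, 5 visits ≈ 11475
records each) and fit the nested model on each; the calibration
bracketing test uses 8 replicate full-size cohorts. These sizes are the
package's chosen balance between Monte-Carlo precision and a test suite
that runs in minutes.

## Known limitations

- The HRF-volume effect is intrinsically hard to estimate: ~2% of spots
  carry HRF, so its coefficient has a per-cohort SE of roughly 1.2–1.7 dB
  per 10⁻³ mm³ (comparable to the uncertainty reported for the cohort the
  generator emulates), and the 0–34 dB clamp plus staircase quantization
  and ROI measurement error attenuate it mildly.
- The eccentricity effect (0.086 dB/deg) is small relative to its
  sampling variability at 51 eyes; single-cohort estimates scatter with
  SD ≈ 0.02 dB/deg.
- Bonferroni on sector contrasts is conservative; with the default grid
  only the central and inner subfields contain stimuli (max eccentricity
  4° = 1.2 mm), so outer-ring contrasts are only available with custom
  grids.
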