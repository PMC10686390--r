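# mpstruct

Point-to-point structure–function analysis for non-exudative age-related
macular degeneration (AMD): does the drusen and hyperreflective-foci (HRF)
load *directly beneath* a microperimetry stimulus depress the sensitivity
of the overlying photoreceptors?

The package is written for retinal-imaging and visual-psychophysics
researchers who want a fully seedable, testable re-implementation of this
analysis. Because clinical microperimetry + OCT datasets of this kind are
not openly deposited, `mpstruct` ships a synthetic cohort generator whose
defaults emulate the published study conditions (35 patients, 51 eyes, up
to 5 quarterly visits, 45 stimuli per eye, ~73% of stimuli overlying
drusen, ~2% overlying HRF, baseline mean sensitivity ≈ 25.7 dB), so every
stage of the pipeline can be verified against known ground truth.

## The model at the core

Each stimulus location is mapped from the microperimeter's fundus photo
into the OCT en-face raster by a least-squares affine estimated from
keypoint pairs. Within a 240 µm circle around the mapped point, lesion
volume is the sum of per-A-scan thicknesses times the unit pixel area
(0.000362 mm² for a 1024 × 97 raster over 20° × 20°); ROI HRF volumes
below 6 × 10⁻⁵ mm³ are set to 0 as sub-detectable. Sensitivity `S` of
spot *s*, eye *e*, patient *p* at visit *v* is then modelled by the
nested linear mixed model (REML, Wald inference)

    S = β₀ + β_d·V_d + β_h·V_h + β_v·visit + β_ecc·ecc
        + β_dv·V_d·visit + β_de·V_d·ecc
        + u_p + u_e(p) + u_s(e) + ε,

with volumes in 10⁻³ mm³, eccentricity in degrees, visit 0–4, and nested
random intercepts for patient, eye-within-patient and
spot-within-eye. Measurements are produced by a simulated 4-2-1 staircase
(range 0–34 dB) driven by a psychometric observer.

## Worked example

```r
library(mpstruct)
cfg    <- cohort_config(n_patients = 6, n_eyes = 9, n_visits = 3)
cohort <- simulate_cohort(cfg, seed = 42)
cohort
#> synthetic microperimetry-OCT cohort: 9 eyes / 6 patients, 3 visits
#>   1215 stimulus records; baseline mean sensitivity 26.20 dB

records <- extract_spot_features(cohort)   # register, map, quantify ROIs
fit     <- fit_volume_model(records)       # nested mixed model (REML)
fit
#> nested mixed model of retinal sensitivity (REML)
#>   1215 observations; 6 patients / 9 eyes / 405 spots
#>                          estimate     se       z      p    ci_lo   ci_hi
#> (Intercept)               26.7069 0.9795 27.2665 0.0000  24.7871 28.6266
#> drusen_vol_e3mm3          -0.9698 0.1312 -7.3927 0.0000  -1.2269 -0.7127
#> hrf_vol_e3mm3             -7.4179 4.3666 -1.6988 0.0894 -15.9763  1.1406
#> visit                      0.2839 0.0571  4.9693 0.0000   0.1719  0.3959
#> ecc_deg                   -0.1074 0.0827 -1.2991 0.1939  -0.2694  0.0546
#> drusen_vol_e3mm3:visit    -0.0938 0.0369 -2.5395 0.0111  -0.1662 -0.0214
#> drusen_vol_e3mm3:ecc_deg  -0.0174 0.0798 -0.2184 0.8271  -0.1739  0.1390
#> variance components (dB^2):
#>  patient      eye     spot residual
#>   4.9564   0.5485   2.2151   1.9860
#> AIC 4939.8; logLik -2458.9
```

Reading the output: each 10⁻³ mm³ of drusen under a stimulus costs about
1 dB of sensitivity (the cohort was generated with β_d = −0.991, so the
estimate −0.97 ± 0.13 recovers it); the HRF coefficient is large but
noisy at this small example size because only ~2% of stimuli carry HRF;
the positive `visit` term is the perimetric learning effect; the variance
components partition the between-patient / between-eye / between-spot /
residual variability in dB².

Companion analyses: `fit_presence_model()` (presence indicators instead
of volumes), `fit_sector_model()` (ETDRS subfields with
Bonferroni-adjusted pairwise contrasts), `learning_sensitivity()`
(visit-effect refits excluding early visits), `compare_models()` (ML
AIC). A full run — simulate → register → extract → fit, with TIFF/CSV/
JSON artifacts and a manifest — is one call:

```r
run_pipeline(pipeline_config(cfg, master_seed = 42), "out/")
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --seed 42
--out-dir out`.

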