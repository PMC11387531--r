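# prmivim

Parametric response mapping of co-registered IVIM diffusion MRI and
FDG-PET in solid tumors, with a digital-phantom cohort generator so the
whole analysis is testable end to end.

## The problem

In locally advanced cervical cancer under chemoradiation, diffusion MRI
and FDG-PET probe complementary biology: the intravoxel incoherent motion
(IVIM) model decomposes the diffusion signal into tissue water diffusion
(`D`, inversely related to cellular density), a perfusion fraction (`f`)
and a capillary pseudo-diffusion coefficient (`D*`), while PET SUV maps
metabolic activity. Voxel-wise joint analysis of the two — parametric
response mapping (PRM) — splits each tumor into sub-volumes such as
SUV^hi D^lo (metabolically active, high cellularity) and asks whether
their relative sizes at baseline predict the tumor-volume change (ΔGTV)
seen on treatment. This package implements that pipeline for researchers
working with multi-b-value DWI and PET volumes in NIfTI format.

## What is inside

- **IVIM fitting** — the bi-exponential forward model
  `S(b) = S0·[f·e^(−b·D*) + (1−f)·e^(−b·D)]`; a Bayesian fitter
  (dense-grid marginalization with analytic S0/noise marginalization,
  posterior-mode point estimate, posterior SDs) and a segmented
  least-squares reference fitter with iterated perfusion subtraction.
- **Registration** — 6-DOF rigid alignment by normalized mutual
  information (Parzen joint histogram, multi-resolution Nelder-Mead),
  plus world-coordinate trilinear/nearest resampling; transforms are
  4×4 row-major text matrices.
- **PRM** — population-mean thresholds (μ_SUV, μ_D, μ_f) from the
  pre-treatment cohort, four-class joint-histogram labelling for
  SUV×D, SUV×f and D×f, relative volume percentages, PNG overlays in the
  conventional cyan/magenta/red/green scheme.
- **Cohort statistics** — ΔGTV, paired Wilcoxon tests (exact by
  enumeration at small n, even under ties), Spearman associations,
  voxel-wise SUV–IVIM correlations, Table-1-style summary and
  association tables as TSV.
- **Digital phantoms** — ellipsoidal rim/core tumors with ground-truth
  D/f/D*/S0/SUV maps, Rician-noise DWI, PET on a deliberately offset
  grid with the true transform stored, on-treatment follow-up with
  volume shrinkage and coupled response; whole cohorts from one seed.

## Worked example

Simulate a 20-patient cohort under typical cervical-cancer conditions,
write it to disk as NIfTI + sidecars + manifest, and run the full
pipeline (Bayesian fits, registration, thresholds, PRM, statistics):

```r
library(prmivim)
cohort <- simulate_cohort(cohort_params(seed = 1))
cfg <- write_cohort(cohort, "cohort20")
res <- run_pipeline(cfg)   # ~10 min on one CPU
res$paired
```

```
    variable    pre_mean      on_mean   V            p
1 gtv_pre_cc 73.42080000 40.089600000   0 1.427979e-04
2          D  0.00103926  0.001085063 172 1.068878e-02
3          f  0.17097728  0.185329769 208 5.722046e-06
4      Dstar  0.02310741  0.019186774   3 9.536743e-06
```

GTV fell from 73.4 to 40.1 cc (p = 1.4e-4) while fitted `D` and `f` rose
(p = 0.011 and 5.7e-6) — the generator built those on-treatment changes
in, and the pipeline recovers their direction and significance from the
noisy images. Baseline associations with ΔGTV
(`res$associations`, Spearman):

```
          variable          r            p  significant
        gtv_pre_cc -0.4442804 0.0497021002         TRUE
                 D  0.6626552 0.0014531761         TRUE
   prm_suv_d_hi_lo -0.7416322 0.0001821683         TRUE
   prm_suv_d_lo_hi  0.7002633 0.0005860464         TRUE
     prm_d_f_hi_hi  0.5347876 0.0151209238         TRUE
     prm_d_f_lo_lo -0.6430990 0.0022230761         TRUE
```

Bigger baseline tumors and larger SUV^hi D^lo sub-volumes shrink more
(negative r); high baseline `D` and large SUV^lo D^hi sub-volumes
predict less volume loss — the radioresistant-sub-volume pattern the
method is designed to surface. Per-patient voxel-wise SUV–IVIM rank
correlations average r = −0.12 (SUV vs D) and −0.03 (SUV vs f): weak
local anticorrelation, matching the generator's targets of −0.15
and −0.08.

## Scientific notes

See the methods vignette (`vignettes/prmivim-methods.Rmd`) for the model
and estimation details, the phantom's design and what it does and does
not emulate, tie-breaking and missing-data conventions, and known
limitations (notably the right-skew of voxel-wise `f` and `D*`
estimates at clinical SNR, which inflates their tumor means relative to
ground truth).
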