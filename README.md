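# ulfdwi

Simulation and analysis of diffusion MRI at ultra-low magnetic field.

Portable permanent-magnet MRI systems (~64 mT) make diffusion imaging and
tractography cheap and mobile, but they operate in a physics regime that
high-field tooling assumes away: the static field carries a built-in
gradient of up to 1.4 mT/m — about 7% of the diffusion-encoding gradient —
so the realised b-value varies across the field of view and with encoding
direction; SNR is low enough that Rician magnitude noise suppresses
apparent FA and MD; and long fast-spin-echo readouts blur the image through
an echo-train-length-dependent point-spread function.

`ulfdwi` is for researchers studying this regime. It provides:

* **a forward simulator**: digital fibre phantoms (arcs, crossings, CSF,
  cortex-like rind, with exact ground truth) and the acquisition physics —
  per-voxel, per-direction b-scaling from a background gradient field,
  multiplicative B1 bias, echo-train PSF blur, Rician noise — under the
  18-direction, b = 945 s/mm², monopolar PGSE protocol
  (δ = 35 ms, Δ = 42 ms, 3 mm voxels);
* **the corrections**: N4-style B1 bias estimation from the b = 0 image,
  and the exact inverse of the background-gradient signal model
  S′ = S0 exp(−a(r)·b·D), i.e. S = S0 (S′/S0)^(1/a), with both a lobe-only
  and an echo-time cross-term model of a(r, û). The cross-term model at the
  scanner's stated extreme (1.4 mT/m parallel, 7% of the encoding gradient)
  yields an uncorrected ADC error of **16.1%** (the lobe-only model: 14.5%);
* **the analysis chain**: log-linear WLS and robust (RESTORE) tensor
  fitting with FA/MD/direction-encoded-colour maps, constrained spherical
  deconvolution at harmonic order 4 (single- and two-tissue), fODF peak
  extraction, anatomically constrained deterministic/probabilistic
  tractography, ROI filtering, and track-density mapping;
* **quantitative evaluation** against phantom ground truth: scalar bias,
  angular error, hemispheric asymmetry, per-bundle Dice overlap and
  centreline deviation, orchestrated by `run_pipeline()` which runs the
  corrections both ON and OFF and reports paired metrics.

File formats: NIfTI-1 images, FSL-dialect bvals/bvecs, MRtrix TCK
tractograms, flat key-value configuration, JSON reports.

## Worked example

Simulate a 32³ phantom acquisition with the default background-gradient and
B1 bias fields, run the full pipeline with corrections ON and OFF, and
score recovery:

```r
library(ulfdwi)
cfg <- default_config(phantom = list(n = 32),
                      tracking = list(n_seeds = 400, mode = "deterministic"))
rep <- run_pipeline(cfg)
print(rep)
```

```
pipeline evaluation report (seed 1 )
                       name branch            mask         value  units   n
                    md_bias    off single_fibre_wm  1.734739e-07 mm^2/s 152
                    md_rmse    off single_fibre_wm  2.455262e-06 mm^2/s 152
                    fa_bias    off single_fibre_wm -2.937506e-05        152
         angular_error_mean    off single_fibre_wm  2.167013e-01    deg 152
               fa_asymmetry    off              wm  6.184289e-03        356
                    md_bias     on single_fibre_wm -1.897354e-19 mm^2/s 152
                    md_rmse     on single_fibre_wm  6.820922e-18 mm^2/s 152
                    fa_bias     on single_fibre_wm  9.349247e-17        152
         angular_error_mean     on single_fibre_wm  0.000000e+00    deg 152
               fa_asymmetry     on              wm  2.282720e-04        356
              dice_arc_left     on        arc_left  7.027027e-01         67
    centreline_dev_arc_left     on        arc_left  3.997981e+00     mm  67
  centreline_drift_arc_left     on        arc_left  2.841824e-01     mm  67
             dice_arc_right     on       arc_right  7.602339e-01         54
   centreline_dev_arc_right     on       arc_right  3.800436e+00     mm  54
                 dice_cyl_x     on           cyl_x  7.505330e-01        122
                 dice_cyl_y     on           cyl_y  7.505519e-01         73
```

Reading it: with corrections OFF the spatially varying encoding leaves a
small positive MD bias and a measurable hemispheric FA asymmetry in this
noiseless simulation; with corrections ON the tensor metrics return to the
ground truth at numerical precision (the asymmetry index drops ~30-fold).
Each bundle's ROI-dissected track-density map overlaps its true mask with
Dice ≥ 0.70, and arc streamlines deviate from the true centreline by ~0.28
mm net of their offset within the 6 mm tube — the curvature is recovered.

Individual stages are ordinary functions (`default_phantom()`,
`ulf_scheme()`, `simulate_dwi()`, `estimate_bias()`, `correct_background()`,
`fit_dti_wls()`, `csd_fit()`, `track()`, ...) and compose with
`run_pipeline()` bit for bit given the same seeds. A command-line wrapper
lives at `inst/scripts/run_pipeline.R`.

## Notes

The methods vignette (`vignettes/ulf-diffusion-methods.Rmd`) documents the
models, parameter choices, numerical tolerances and known limitations,
including the SH basis convention, the two b-scaling strategies and why the
correction restores (rather than deepens) attenuated signal, and what the
phantom does and does not emulate about real scanner data.
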