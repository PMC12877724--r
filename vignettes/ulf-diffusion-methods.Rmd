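---
title: "Methods: simulating and analysing ultra-low-field diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing ultra-low-field diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulfdwi)
```

## Why ultra-low-field diffusion is different

Diffusion MRI on portable permanent-magnet systems (tens of mT) operates in
a regime that high-field tooling silently assumes away. Three features
dominate:

1. **The static field carries a large built-in gradient.** On the system
   modelled here it reaches about 1.4 mT/m at 8 cm from isocentre — about 7%
   of the diffusion-encoding gradient itself. It adds vectorially to the
   encoding gradients, so the *realised* b-value varies over the field of
   view and with the encoding direction. Ignored, this biases every
   diffusion metric; characterised, it can be corrected retrospectively.
2. **SNR is low and images are magnitudes.** Rician noise rectifies the
   signal near the noise floor, suppressing the apparent attenuation and
   with it the apparent fractional anisotropy (FA) and mean diffusivity
   (MD) in strongly attenuated (high-FA, low-SNR) voxels.
3. **Long fast-spin-echo readouts blur.** T2 decay over the echo train
   attenuates the k-space periphery, giving an echo-train-length-dependent
   point-spread function along the phase-encoded axes.

The package simulates all three mechanisms on digital fibre phantoms with
known ground truth, implements the corrections, and carries the corrected
data through the standard microstructure pipeline: tensor fitting (weighted
least squares and robust RESTORE refitting), constrained spherical
deconvolution (CSD) at harmonic order 4, and anatomically constrained
streamline tractography, scored against the phantom.

## The acquisition model

The protocol frozen into `ulf_scheme()` is a monopolar pulsed-gradient
spin-echo acquisition: one b = 0 volume plus 18 directions at
b = 945 s/mm^2 (lobe duration delta = 35 ms, separation Delta = 42 ms,
effective echo time 84 ms), at 3 mm isotropic resolution. The 18 directions
are arranged by electrostatic repulsion into three groups of six, each group
separately well spread, so a scan terminated after one or two groups still
supports a tensor fit. The per-volume scan-time accounting
(`scan_time(212, 800)` for 212 shots at TR 800 ms) reproduces the
~170 s cost of each diffusion-weighted volume, which is why direction count
is so precious in this regime.

The forward model per voxel and direction u is a fraction-weighted sum of
single-tensor compartments,

S(r, u) = s0 b1(r) [ sum_c f_c exp(-a(r, u) b u' D_c u)
                     + f_csf exp(-a b D_csf) + f_gm exp(-a b D_gm) ],

with multiplicative B1 bias b1(r), the b-scale a(r, u) described next, PSF
blur applied per volume after attenuation, and Rician noise last. The
multi-compartment sum generalises the single-ADC signal equation because
crossing-fibre phantoms require it; for a single compartment the two
coincide.

## The b-scaling factor a(r, u)

Two strategies are implemented behind the same interface
(`b_scale_factor()`, `b_scale_map()`):

* **Lobe-only (default).** The background gradient g(r) adds to the
  encoding lobes only: a = ||G u + g||^2 / G^2 = 1 + 2(g.u)/G + |g|^2/G^2.
  At the 7% parallel extreme this gives a - 1 = 14.49%.
* **Echo-time cross-term.** The background gradient acts throughout the
  echo, not just during the lobes. Writing the b-value as the time integral
  of the squared zeroth gradient moment (with the effective sign flip at
  the refocusing pulse), the linear-in-g term scales as
  2 kappa (g.u)/G with kappa = I_Gg / I_GG computed from the pulse timing
  (`pgse_cross_ratios()`). For delta = 35 ms, Delta = 42 ms and TE = 84 ms
  with lobes symmetric about the refocusing pulse, kappa = 1.15 exactly,
  so the 7% parallel extreme gives a - 1 = 16.1%. The model is linear in g
  by default (the b-scaling is then a pure linear scaling of the prescribed
  b); the quadratic background-only term (kappa_bg |g|^2/G^2, below 1% at
  these field strengths) is available as an option.

The correction (`correct_background()`) inverts the forward model exactly:
S = S0 (S'/S0)^(1/a), using the b = 0 image as the reference that separates
encoding from other contrast. The printed form of the correction equation
is typographically ambiguous (a missing multiplicand and an ambiguous
exponent sign); the implementation uses the algebraically exact inverse,
which is equivalent to the multiplicative form
S = S' exp(log(S'/S0)(1/a - 1)). Signals are clamped at 1e-6 of S0 before
the log and voxels whose S0 sits below that floor are left untouched. Note
the direction of the correction: when a > 1 the realised diffusion
weighting was stronger than prescribed, the observed attenuation overstates
D, and the corrected signal is restored *above* the observed one —
monotonically so in a.

## Corrections around it

**B1 bias.** `estimate_bias()` is a deliberately simplified N4-style
estimator: in the log domain it alternates a crude piecewise-constant
tissue model (deterministic 1D k-means, three classes) with extraction of
the smooth residual field by mask-normalised Gaussian smoothing,
*accumulating* smoothed residuals so that the fixed point has vanishing
smoothed residual — which is what makes a second estimate on corrected data
return a unit field (near-idempotence, verified to < 1%). The in-vivo
pipeline treats bias correction as an off-the-shelf step; only its contract
matters downstream, because a field multiplying all volumes equally cancels
in S/S0.

**Noise level.** `estimate_noise_sigma()` uses the Rayleigh-median relation
sigma = median(background)/1.1774 on an automatically detected (or
supplied) signal-free region. The in-vivo practice of manually adjusting
sigma for visual consistency has no algorithm, so it is exposed as an
explicit `override` argument and never applied silently.

## Analysis choices

**Tensor fitting.** Log-linear two-pass weighted least squares (weights =
squared predicted signals); the b = 0 volume participates as a design row
estimating ln S0. RESTORE refitting uses Geman-McClure weights on
signal-domain residuals with scale C sigma (C = 3), at most 20 IRLS
iterations, convergence at relative parameter change below 1e-6, outlier
exclusion at 3 sigma and a final plain refit on retained volumes; voxels
retaining fewer than 7 rows are flagged invalid rather than silently
fitted. Note that no robust fitter can be expected to identify a corrupted
*majority* of volumes (breakdown); the invalid flag is the honest output in
that regime. Negative eigenvalues from noisy fits are retained (flagged,
not clipped).

**Spherical harmonics and CSD.** The real, even, antipodally symmetric
basis is orthonormal with l ascending and m from -l to +l (m < 0 paired
with sine terms); dialects differ between toolkits, so the convention is
pinned by tests against an independent associated-Legendre implementation.
Order lmax = 4 (15 coefficients) matches 18 measured directions. The
single-fibre response is estimated from a high-FA voxel population
(threshold 0.7, at least 20 voxels — the phantom stand-in for manual
midline selection), pooled by the angle between encoding direction and
principal eigenvector and projected onto zonal harmonics. For an FA-0.87
tensor the best possible lmax-4 zonal profile has ~0.7% RMS truncation
error, which the estimator attains on clean populations; partial-volume
contamination of a realistic selection raises the pooled residual without
harming deconvolution. CSD solves the Funk-Hecke-diagonalised system with
iterative soft non-negativity: amplitudes on a 300-direction
electrostatically optimised constraint set (shipped as a fixture for
bit-reproducibility) below tau = 0.1 x the mean initial amplitude are
quadratically penalised, with strictly negative amplitudes carrying 10x
weight; the user-facing weight lambda = 1 is scaled by the data-block norm.
Residual negative amplitudes stay within 1% of the peak. With a CSF
response, a second isotropic compartment is fitted jointly — a single shell
plus b = 0 supports exactly two tissues, so the three-tissue variant used
on richer data is deliberately reduced to WM + CSF here. Peaks are strict
local maxima on a 724-direction sphere, refined by projected gradient
ascent, with a 0.5 relative amplitude cutoff and 25 degree separation.

**Tracking.** The tracker is a first-order fODF sampler with a curvature
cap, not a re-implementation of second-order arc sampling: the in-vivo
pipeline treats the tracker as an off-the-shelf component and what is
scored here is phantom-geometry recovery. Defaults: step 0.5 voxel
(1.5 mm), 45 degrees per step, amplitude cutoff 0.1 x the global maximum
fODF amplitude, length window 10-250 mm, bidirectional growth,
1000 rejection-sampling trials before an "amplitude" termination.
Anatomical constraints interpolate the tissue maps: dominant CSF rejects
the whole streamline, dominant GM terminates and accepts, leaving the grid
accepts if the minimum length is met. Each streamline derives its RNG
stream from (global seed, seed index), so results are order-independent
and bit-reproducible. SH coefficients and tissue fractions are
trilinearly interpolated; all streamline coordinates are world mm.

## The phantom and what passing means

`default_phantom()` is mirror-symmetric about the mid-sagittal plane: one
C-shaped arc bundle per hemisphere (radius 28 mm, tube radius 6 mm), two
straight bundles crossing at 90 degrees in an axial plane, a central CSF
ellipsoid and a spherical cortex-like GM rind, embedded in deep GM inside
a spherical head. Tissue fractions come from 2^3 supersampling of the
analytic geometry, which produces genuine partial-volume boundaries and a
non-empty GM/WM interface for seeding. WM compartments default to
eigenvalues (1.7, 0.2, 0.2) x 10^-3 mm^2/s (FA 0.8704, MD 0.7 x 10^-3);
CSF is isotropic at 3.0 x 10^-3, deep/cortical GM at 0.8 x 10^-3. The
mirror symmetry gives hemispheric-asymmetry metrics a zero ground truth.

Per-bundle ground-truth masks are *occupancy* masks (bundle fraction
> 0.1): at 3 mm voxels a 6 mm tube consists mostly of partial-volume
voxels, and a majority-occupancy mask would miss roughly half of the
volume the bundle genuinely occupies. Track-density maps are thresholded
at 5% of their maximum before Dice overlap (stated in every report). Arc
recovery is additionally scored by the distance from streamline vertices
to the true centreline, reported both raw and net of each streamline's
median offset — a streamline running parallel to the centreline anywhere
inside the finite-thickness tube has zero net deviation, so the net value
isolates curvature and drift error from the tube's own cross-section.

What the phantom does *not* emulate: scanner reconstruction (EMI
filtering, compressed-sensing reconstruction, coil combination), geometric
distortion and registration error, eddy-current or motion-induced
volume-to-volume modulation, f0 drift, or realistic cortical folding.
Passing tests therefore demonstrate the correctness of the modelled
physics and of the analysis chain, not robustness to everything a real
scanner does.

## Noise conditions and problem sizes

The default pipeline configuration is noise-free: exact recovery claims
(background-correction round trips at 1e-8, machine-precision tensor
recovery) are only meaningful without noise. Rician artifact studies use
`noise$snr` — defined as s0/sigma in b = 0 white matter — with SNR 15 as
the representative ultra-low-field operating point and sweeps over
{5, 10, 20, 40} for bias-direction experiments. The Rician FA/MD bias
saturates to zero above SNR ~ 20 at b = 945, so monotonicity between
adjacent high-SNR points is asserted only up to the sampling noise of the
voxel population.

Problem sizes were chosen as the smallest that leave each behaviour
clearly measurable: unit tests run on 24-32 voxel grids; the end-to-end
evaluation runs the default 48^3 grid (3 mm voxels, 144 mm field of view)
with 1000 interface seeds, completing in a few minutes on one CPU. A
higher-fidelity reference acquisition (more directions, higher SNR, e.g.
`ulf_scheme(n_dirs = 60, n_groups = 1)` with noise off) is available
through the same configuration surface for direction-count degradation
experiments.

## Reproducibility

All randomness flows from a single seed through named per-stage substreams
(`scheme`, `bias`, `noise`, `seeds`, `track`), and per-streamline streams
are keyed by seed index. Rerunning `run_pipeline()` with the same
configuration reproduces every number in the report bit for bit; the
report serialises to JSON with its configuration and seed embedded.
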