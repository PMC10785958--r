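---
title: "Methods: optically navigated tFUS simulation and targeting-error analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optically navigated tFUS simulation and targeting-error analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transcranial focused ultrasound (tFUS) neuromodulation steers a focused bowl
transducer at a brain target through the intact skull. Optical
neuronavigation predicts where the acoustic focus will land; acoustic
simulation predicts how the skull displaces and attenuates it; and a
measured focus (in vivo, MR acoustic radiation force imaging) tells you
where it actually landed. `tfusnav` implements the full in-silico chain —
navigation geometry, subject-specific acoustic model, wave simulation, focus
localization, error metrics, and measured-focus re-targeting — together with
a synthetic-scene generator so every stage can be exercised against known
ground truth without hardware.

# Coordinate frames and the transform hierarchy

Five right-handed RAS millimetre frames are chained by rigid transforms
`^B T_A` (mapping frame A into frame B):

- image (I): the anatomical (T1-like) volume;
- physical (P): the optical tracking camera's world;
- tracker (T): the rigid tool mounted on the transducer;
- ultrasound (U): origin at the transducer's geometric focus, +z along the
  propagation axis;
- simulation (S): the acoustic grid.

The pose of the simulation grid in image space is
`^I T_S = ^I T_P  ^P T_T  ^T T_U  ^U T_S`. `^I T_P` comes from paired-point
fiducial registration, `^P T_T` from the camera, `^T T_U` from a one-time
focus calibration of the transducer relative to its tracker, and `^U T_S`
from a one-time alignment of the transducer model to the imaged transducer,
repeated (three times by default) and averaged. Any empirical focus bias
(for the H115MR hardware, a `[2, 0, 4]` mm offset validated against MR
thermometry) is folded into `^T T_U` as a translation expressed in the
ultrasound frame; we fix the convention that the bias is a translation in U
applied after the geometric calibration — the alternative (pre-multiplied in
T) differs only by the tool rotation and would be absorbed by the same
calibration procedure.

Rotations are stored as matrices and re-orthonormalized (polar
decomposition) only when accumulated drift exceeds `1e-9`; quaternions are
used transiently for rotation averaging. The `^U T_S` average is the
arithmetic translation mean plus the quaternion chordal mean (principal
eigenvector of the sign-aligned outer-product sum) — the standard,
order-invariant choice for small-angle spreads; inputs more than 30 degrees
apart are refused as outliers rather than averaged.

# Fiducial registration

Six fiducials are localized in image and physical space. `fit_rigid()` is
the closed-form Kabsch/SVD solution with the determinant-sign correction, so
reflections are never returned; the fiducial registration error (FRE) is the
root-mean-square (not mean) residual distance. Correspondence is found by
`match_fiducials()` through exhaustive search over all `n!` permutations,
each scored by a full fit — exact at navigation fiducial counts (720
permutations at n = 6, bounded at n ≤ 8). Symmetric constellations that tie
within `1e-9` mm emit a warning and keep the lexicographically first
permutation. Collinear sets are rejected by a singular-value rank check.

# Transducer model

The bowl is a single-element spherical cap, default radius of curvature
63.2 mm and aperture diameter 64 mm. `make_bowl()` rasterizes the cap as the
set of voxels whose centres lie within half the voxel extent of the sphere,
measured along the local surface normal (a supercover criterion): the shell
stays one-to-two voxels thick with no through-holes, and every voxel centre
is within half a voxel diagonal of the ROC sphere. Poses are applied by
re-rasterizing the analytic cap at the transformed focus and axis
(`place_transducer()`), never by rotating the voxel mask, which would open
aliasing holes in the source. A 3 × 3 × 3 focus-marker cube at the geometric
focus supports visual alignment and is excluded from the acoustic source.

A note on surface-area book-keeping: a raw voxel count times `spacing^2`
overestimates any digitized surface's area by the mean L1 norm of the unit
normal (up to √3), irrespective of spacing. `bowl_area_estimate()` therefore
weights each voxel by `spacing^2 / |n|_L1`, which converges to the analytic
cap area `2π·ROC·h_cap`; the raw count still scales as `spacing^-2`, which
is what the resolution tests check.

# Acoustic medium

The simulation grid defaults to water (1500 m/s, 1000 kg/m³, 0 dB/cm/MHz).
Phantom ("tissue") voxels keep water speed and density and receive an
absorption of 0.2 dB/cm/MHz — one third of the 0.6 dB/cm/MHz attenuation
measured in agar-graphite material, the remainder being scatter. Skull
voxels are segmented from CT by Otsu's method (256-bin between-class
variance; exact ties resolve to the middle of the tied run, which places
the threshold midway between well-separated modes; volumes with no
bone-like mode — Otsu threshold under 150 HU — yield an empty mask with a
warning), keeping the largest 26-connected component. Hounsfield units map
linearly to porosity, `φ = 1 − clamp(HU, 0, HU_max)/HU_max` with
`HU_max = 1000` by convention (configurable — it is a modelling constant the
CT calibration literature sets near cortical bone). Properties interpolate
between the water and cortical-bone endpoints (3100 m/s, 2200 kg/m³):
speed and density linearly in bone fraction `1 − φ`, absorption from
0.02 (dense) to 2.7 dB/cm/MHz (fully porous) with a configurable exponent on
φ (default 1, i.e. linear; the literature is not unanimous on this
exponent). Where skull and tissue masks overlap, skull wins with a warning.
Property grids are asserted to stay within the table's endpoints after
assembly.

# Field solver

The solver computes the steady-state continuous-wave field of the bowl at
the drive frequency by one-way split-step angular-spectrum marching along
+z. At each plane, bowl voxels are injected in the spatial-frequency domain
with the `k/kz` obliquity weight that makes a voxel sheet radiate as a
monopole layer — with that weight, marching a homogeneous medium evaluates
exactly the Rayleigh–Sommerfeld integral of the discretized source, which is
why the solver is validated against an independent Rayleigh-integral oracle
rather than against itself. Propagation uses the exact non-paraxial transfer
function `exp(i·kz·dz)`; lateral spatial frequencies above 95 % of `k`
(evanescent and near-grazing) are discarded; a raised-cosine apodization of
10 voxels at the lateral edges suppresses FFT wrap-around. Heterogeneity is
applied per marching step as phase screens (local wavenumber minus
background) and absorption screens (dB/cm/MHz × f[MHz] converted to Np/mm).
The RMS pressure `|p|/√2` is recorded over the whole grid.

This scheme was chosen over a time-domain pseudospectral stepper because the
field of interest is single-frequency and forward-propagating: it resolves a
144 × 144 × 192 grid in about a second of CPU, is exactly linear in source
amplitude, and passes the oracle gate (peak position and focal profile)
directly. The price is physics it does not model: reflected and
backward-travelling waves (standing waves, skull reverberation, multiple
internal reflections), density-contrast transmission losses at interfaces,
shear conversion in bone, and any nonlinearity. Transmitted-beam
refraction, aberration and absorption — the effects that move and attenuate
the transcranial focus — are modelled. Absolute pressures are therefore not
calibrated against the measured source; all targeting metrics are spatial
and insensitive to the overall scale. The absorption frequency power law is
fixed linear-in-f, consistent with dB/cm/MHz units.

The sampling rule `(c/f)/Δx ≥ 7` points per wavelength in water is enforced;
the solver refuses under-resolved grids. Two presets share the same 72 × 72
× 96 mm extent and ppw ≈ 7.48: the full scale (288 × 288 × 384 at 0.25 mm,
802 kHz) and the desk scale (144 × 144 × 192 at 0.5 mm, 401 kHz). All tests
run at desk scale, which keeps a full pipeline run (three to four
simulations plus resampling) under half a minute; full scale is supported
but not exercised by the default suite.

# Focus localization and error metrics

The focus is the maximum voxel of the RMS field (`focus_max()`). When the
global maximum falls outside the (eroded) tissue mask — at the skull, where
transcranial fields often peak — the maximum inside the mask eroded by a
digital ball (default radius 2 voxels; the kernel shape is our choice, the
operation itself is standard practice) is taken instead, so the reported
focus is always strictly inside tissue. Ties break to the lowest linear
index with a warning. A second centre estimator,
`focus_centroid_halfmax()`, returns the unweighted centroid of the
26-connected half-maximum component containing the peak.

Every error metric decomposes along the transducer axis: axial = |Δ·axis|,
lateral = ‖Δ − (Δ·axis)axis‖, total² = axial² + lateral². The lateral
component is defined in the axis frame, so it generalizes to tilted poses
and reduces to the in-plane X/Y norm for axis-aligned ones. Axial components
are reported as absolute values. Four metrics are computed: `TRE_Opti_ARFI`
(predicted vs measured), `Error_Opti_Sim` (simulated vs predicted),
`Error_Sim_ARFI` (simulated vs measured), and `Error_SimUpdated_ARFI` after
the correction.

The distance-vector correction translates the modeled transducer by
(measured − predicted) and re-simulates; rotation is deliberately not
corrected.

Two interacting design choices deserve emphasis, because the focal physics
forces them. At the desk scale the focal peak of this bowl sits about 3 mm
proximal of the geometric focus (focusing-gain physics, stronger at lower
frequency), and the half-maximum axial lobe is long (≈ 31 mm) and
asymmetric, so its centroid sits several millimetres distal of the peak.
Consequently:

1. **The tracked focus point is calibrated empirically.** The pipeline
   simulates the canonical pose in water once and projects the *measured
   peak position* — not the geometric focus — through the hierarchy as the
   predicted focus. This is the in-silico analogue of validating the
   tracked focus against MR thermometry and folding the observed offset
   into the calibration, and it is what makes a noise-free synthetic scene
   close to zero error.
2. **Metrics default to the maximum-voxel focus definition** for all four
   metrics. The half-max centroid estimator is provided and tested, but its
   systematic axial offset from the peak would dominate sub-voxel recovery
   checks; it remains available for users who want the segmentation-based
   centre.

With a water focus calibration but an absorbing phantom in the true medium,
the simulated focus shifts slightly proximal of the calibrated prediction;
the pipeline then reports a small axial `Error_Opti_Sim` that survives the
vector correction — the same signature physical phantom experiments show.

# Synthetic scenes

`make_phantom_scene()` builds the full input set of a tracked session: a
cylindrical agar-like phantom in a T1-like volume, six fiducials on the mold
surface (exact in image space, Gaussian-perturbed in physical space with
configurable σ), fixed general-position hierarchy links, three noisy
`^U T_S` alignments (perturbation rotations pivot about the focus, where a
manual model alignment is anchored), and a tracked pose carrying an injected
targeting error. The default injected error is a 3.5 mm translation —
mid-range for reported optical tFUS navigation accuracy — applied to the
tracked link `^P T_T`, where real tracking error enters, but expressed so
its image-frame effect is exactly the configured vector. All randomness
derives from one seed; the same seed reproduces the scene bit-exactly.

`make_skullcap_ct()` emulates an ex vivo skull cap as a spherical-shell
segment (outer radius 40 mm, thickness 6 mm, opening toward the transducer)
with cortical tables near 1400 HU, a trabecular dip near 700 HU mid-shell,
and Gaussian HU noise. The shell is deliberately off-centre from the focus
so the beam crosses it at varying thickness and obliquity — a concentric
shell would add a uniform delay and neither shift nor aberrate the focus.
The measured (MR-ARFI stand-in) focus is the maximum of the true-pose
simulated field, optionally Gaussian-perturbed to model ARFI voxel size and
manual selection.

What the generator does **not** emulate: real skull geometry and diploë
texture, CT beam-hardening and partial-volume artefacts, MR distortion,
fiducial localization bias (only isotropic noise), camera-calibration drift,
and any MR displacement physics. Passing the suite therefore demonstrates
the pipeline's geometric and numerical correctness under controlled
conditions, not clinical targeting accuracy: the millimetre-scale residuals
real skulls produce arise from physics (reverberation, shear, registration
bias) that the scenes intentionally exclude.

# Numerical choices and degenerate inputs

- Transform orthonormality tolerance `1e-9` (re-orthonormalize above it;
  reject above `1e-6`); reflections rejected outright.
- Registration requires ≥ 3 non-collinear points (singular-value check at
  relative `1e-9`).
- Trilinear resampling snaps coordinates within `1e-9` of the lattice so
  integer-voxel poses reproduce data exactly; out-of-field voxels fill with
  the background (0 HU / 0).
- Otsu ties average; thresholds below 150 HU are treated as "no bone".
- Porosity outside [0, 1] clamps with a warning; `HU_max ≤ 0` errors.
- Zero source amplitude short-circuits to a zero field; non-finite field
  values abort with the plane index.
- Empty eroded masks error with a suggestion to lower the radius.

# Reproducibility and problem sizes

Every stochastic element (scenes, noise draws, Monte-Carlo tests) is seeded
explicitly. The test suite and the acceptance script run entirely at desk
scale: the solver grid is 144 × 144 × 192, Rayleigh oracle comparisons use
81 on-axis points, registration Monte-Carlo uses 200 scenes, and the
decomposition identity is checked on 1000 random pairs. The pipeline writes
deterministic artifacts: identical (scene, seed) inputs give byte-identical
reports.
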