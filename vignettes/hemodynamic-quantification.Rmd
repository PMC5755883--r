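---
title: "Quantifying intra-aneurysmal hemodynamics from voxel velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-aneurysmal hemodynamics from voxel velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuflow)
```

## The problem

A flow diverter is a braided stent placed across the neck of an intracranial
aneurysm to redirect blood along the parent artery; treatment success shows up
as a collapse of the intra-aneurysmal flow. Both 4D phase-contrast MRI and CFD
deliver the same raw object — a time-resolved, three-component velocity field
sampled on a regular grid — and the clinically interesting quantities are a
small set of scalars computed from it inside the segmented aneurysm sac:

* **U** — the mean velocity magnitude over sac voxels at the systolic peak
  (m/s). The parent artery is always excluded, otherwise the jet through the
  neck dominates the average.
* **E** — the intra-aneurysmal kinetic-energy measure
  $E = \sum_{i=1}^{N} |u_i|^2$ over the $N$ sac voxels (m²/s²). This is
  deliberately a *sum*, not a mean: its absolute value scales with the
  sampling density, so only relative changes between acquisitions on the same
  grid are meaningful. The package reports its cycle average by default.
* **R** — planar recirculation: with vorticity $\omega = \nabla \times u$,
  $R = \iint \omega \cdot n \, \mathrm{d}A$ over a bounded cross-section of
  the sac (mm²/s). Its cycle mean is $R_m = \frac{1}{T}\int_0^T |R|\,
  \mathrm{d}t$; the absolute value makes $R_m$ insensitive to the sign
  convention of the plane normal, while per-frame $R$ stays signed.
* **WSS / nWSS** — wall shear stress, i.e. dynamic viscosity times the wall
  shear rate, per wall triangle (Pa); and its distribution normalized by the
  maximum over the aneurysm sac, with ≥ 0.75 conventionally read as "high"
  and ≤ 0.25 as "low".

Treatment effect is then summarized per case as relative reductions
$\Delta X = 100\,(X_{\text{pre}} - X_{\text{post}})/X_{\text{pre}}$ for
$X \in \{U, E, R\}$, reported as integer percent.

## Discretization choices

The velocity container stores one signed component volume per direction per
frame, in m/s, with voxel-center sampling, 0-based indices, and a 4×4 affine
mapping index to world millimetres (the NIfTI convention). Defaults mirror a
realistic phase-contrast protocol: 0.53 × 0.53 × 0.60 mm voxels and 71 ms
frames.

**Vorticity.** Second-order central differences wherever the full ±1 stencil
is fluid; first-order one-sided differences at fluid voxels bordering the
wall; NA where no fluid neighbour exists along an axis. Each partial
derivative uses its own axis spacing, so anisotropic voxels are exact. Wall
and exterior voxels are *never* treated as zero velocity: partial-volume
corrupted data near the wall should be excluded, not fabricated. A fluid
region thinner than two voxels along any axis cannot support any stencil and
is a hard error naming the axis.

**Plane integration.** The recirculation surface is not implied by the field;
it is a required input (a point, unit normal, and a disc radius or polygon),
defaulting to the sac's central cross-section: through the sac centroid,
orthogonal to the grid axis of largest sac extent (earliest axis on ties).
The integrand is sampled on a regular in-plane grid (default pitch 0.25 mm)
by trilinear interpolation; samples outside the fluid labels get zero area
weight. Interpolation cells with some non-fluid corners renormalize the
trilinear weights over the fluid corners rather than inventing zeros. The
phantom ground truth uses a reference disc of radius 0.7 × sac radius so that
every interpolation cell is strictly interior — recovery against the closed
form $2\Omega A$ is then limited only by in-plane quadrature (< 1% at the
default pitch).

**Cycle averages.** Frame times are window midpoints within one cardiac cycle
of length $T$. Averaging uses the trapezoidal rule with periodic closure (the
interval from the last frame wraps to the first across $T$), divided by $T$.
The pulsatile pump makes the cycle periodic by construction, so the wrap term
is the natural closure; a constant series averages to exactly that constant
for any frame count.

**Wall shear rate.** The wall surface is a triangle mesh with outward
normals. For each triangle centroid, velocity is sampled along the inward
normal at distances $d$ and $2d$ ($d$ defaults to one voxel diagonal), the
normal component is projected out, and the shear rate is estimated with the
one-sided quadratic derivative consistent with no slip at the wall,
$\dot\gamma \approx (4 u_t(d) - u_t(2d)) / (2d)$. This estimator is exact for
linear *and* parabolic near-wall profiles; the single-point secant
$u_t(d)/d$, kept as an option, underestimates a Poiseuille wall gradient by
the factor $1 - d/2a$ (about 24% at $d \approx 0.96$ mm in a 2 mm-radius
vessel), which is why it is not the default. Elements whose inward samples
leave the fluid mask are flagged invalid and excluded from all maxima. The
normalization maximum for nWSS is taken over sac-adjacent elements only
(centroid nearer to a sac voxel than to any parent-artery voxel); elements on
the parent artery can therefore exceed 1 when their stress tops the sac
maximum.

**Rounding.** Reduction percentages are rounded half away from zero to
integers. Against the published per-case pre/post table this reproduces 16 of
the 18 printed integer cells; the two exceptions (one $\Delta U$ cell and one
$\Delta E$ cell of the same case) were evidently computed from unrounded
source data, and `reproduce_table4()` reports them explicitly rather than
failing silently.

## What the phantoms emulate

No public velocity data exist for this kind of study, so the package ships
analytic phantoms whose ground truth is known in closed form:

* `make_tube_phantom()` — a straight parent-artery tube with a pulsatile
  Poiseuille profile $u(r,t) = u_{\max}(t)(1 - r^2/a^2)$. Exact wall shear
  stress $\eta\, 2 u_{\max}/a$, exact flow rate, zero transverse vorticity.
* `make_sac_phantom()` — the tube plus a spherical sac joined through a neck.
  Pre-treatment (`"vortex"`): solid-body rotation about the neck-parallel
  axis, $\omega = 2\Omega$ exactly, a low-velocity core on the axis, speeds
  capped at 0.9 × VENC so phase wrapping stays opt-in. Post-treatment
  (`"attenuated"`): the rotation is replaced by a uniform weak seepage toward
  the neck whose magnitude is $k$ times the vortex-mode mean sac speed — the
  sac average drops by exactly $k$ and the vortex disappears, which is the
  measured consequence of diverter placement (the stent braid itself is out
  of scope).
* `apply_fd_attenuation()` — voxel-wise scaling of sac velocities by $k$,
  giving the exact expectations $\Delta U = \Delta R = 100(1-k)$ and
  $\Delta E = 100(1-k^2)$ used as a scaling-law oracle.
* `add_pcmri_noise()` — seeded Gaussian noise per component plus wrapping of
  components beyond ±VENC by multiples of 2 VENC. Additive Gaussian is the
  standard first-order phase-contrast noise model; Rician magnitude effects
  are not modeled.

Parameter defaults are the study conditions where stated (voxel size,
temporal resolution, VENC 1 m/s, mean inlet velocity 0.25 m/s) and a
physiologic choice where not: the cycle length is 14 × 71 ms = 0.994 s
(roughly 60 bpm), the waveform is an offset sinusoid
$1 + 0.5\sin(2\pi t/T)$ because only flow rate and peak velocities are
reported for the pump and a sinusoid has closed-form cycle averages, and the
sac vortex defaults to $\Omega = 5\,\mathrm{s^{-1}}$. No single $\Omega$
matches both the published sac velocities and the published recirculation
magnitudes (their integrand is not solid-body), so the default favours clean
closed forms over magnitude mimicry.

What passing tests on these phantoms shows: the operators converge to the
right continuum quantities on resolved, noiseless fields, the reduction
arithmetic is exact, and the pipeline is deterministic end to end. What they
cannot show: accuracy on real PC-MRI data with partial-volume corruption,
phase offsets, acceleration artefacts, or segmentation error — absolute
in-vivo velocity fields are not reproducible at desk scale, which is why the
published comparison is reproduced from its printed per-case table rather
than from raw images.

## Problem sizes and determinism

The default phantom grid is about 51 × 21 × 25 voxels (≈ 1600 sac voxels)
with 14 frames — large enough that boundary voxels are a small minority,
small enough that a full pre/post pipeline run takes seconds. All generators
are deterministic for a fixed spec and seed; the only stochastic step is the
optional measurement noise, which is seeded. Reports serialize with fixed
formatting so reruns are byte-identical.

## Known limitations

* The WSS estimate inherits the resolution limit of voxel data near walls;
  at clinical PC-MRI resolution it is a distribution-level quantity (hence
  nWSS), not a pointwise-accurate stress.
* The voxel-boundary wall surface extracted from a mask is watertight but
  staircase-shaped; its normals are exact only in the axis-aligned sense.
  Analytic or segmentation-derived STL surfaces are preferred where
  available.
* Recirculation depends on the chosen plane; the automatic central
  cross-section is a reproducible convention, not a claim about the vortex
  axis.
* Kinetic energy is grid-dependent by construction and must never be
  compared across different resolutions.
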