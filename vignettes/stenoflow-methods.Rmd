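---
title: "Methods: pressure drop, FFR and helical flow in stenosed coronary bifurcations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pressure drop, FFR and helical flow in stenosed coronary bifurcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoflow)
```

## The problem

Fractional flow reserve (FFR) — the ratio of mean pressure distal to a
stenosis to mean aortic pressure under maximal hyperemia — is the standard
invasive index of the functional severity of a coronary stenosis. In
bifurcation lesions, where the proximal main branch (PMB), distal main
branch (DMB) and a side branch (SB) can all be diseased, FFR readings in the
side branch behave counter-intuitively: the distal bifurcation angle itself
modulates the side-branch pressure drop. `stenoflow` implements a desk-scale
version of the computational study of this effect: a parametric
LAD/first-diagonal bifurcation geometry, diameter-based scaling laws for the
boundary conditions, post-processing of flow fields into pressure drops, FFR
and helicity descriptors, and the quadratic pressure-drop/flow statistics —
with analytic synthetic fields standing in for the 3-D finite-volume solver,
which is deliberately out of scope.

## Geometry model

The three branch axes are great-circle arcs on a sphere of radius 56.25 mm
(the curvature the beating heart imposes on the left coronary tree; vessel
radius over radius of curvature is about 0.03). All three arcs meet at a
single carina point, where the angles are laid out in the sphere's tangent
plane:

* daughter diameters 2.77 mm (DMB) and 2.10 mm (SB); the mother diameter
  follows Finet's fractal branching rule, `0.678 * (2.77 + 2.10) = 3.30` mm;
* the main-branch angle beta (between the upstream PMB axis and the DMB
  axis) is 150 degrees. We measure beta with the clinical convention in
  which a perfectly straight vessel has beta = 180 degrees, so the flow
  direction turns by 30 degrees at the carina;
* the distal angle alpha between the DMB and SB axes takes the values 40,
  55, 70 degrees across the study grid; the SB departs on the opposite side
  of the main-vessel bend;
* the proximal segment is 8 mother diameters (26.4 mm) from inlet to
  stenosis start, matching measured human proximal LAD lengths.

### Lesion shape

The published model states only the throat severity per branch (60 % PMB,
60 % DMB, 40/60/80 % SB as percent diameter stenosis) and a total lesion
length of 12 mm per branch pathway, "affecting all segments". Two choices
were genuinely open and are fixed here once:

* **Axial profile.** The diameter narrows with a raised-cosine bump —
  C1-continuous, symmetric, reaching the full severity at the window
  midpoint. This is the standard smooth idealized-stenosis shape and avoids
  spurious pressure singularities at the lesion ends.
* **Split at the carina.** The 12 mm window is divided 50:50: 6 mm in the
  PMB ending at the carina and 6 mm in each daughter starting at the
  carina, so both the PMB+DMB and the PMB+SB pathways see exactly 12 mm of
  lesion. Each branch portion carries its own full-severity bump with the
  throat at the portion midpoint; this makes the requested severity exactly
  recoverable from the surface mesh (self-measurement closure) and keeps
  the profile C1 along each pathway.

Lesions are eccentric: the plaque occupies the inner (sphere-facing) arc,
so the lumen center is displaced radially *away* from the sphere center by
half the lost diameter and the outer wall stays fixed.

### Tessellation

Each branch is swept as a ring tube along its centerline. The ring frame
uses the sphere's radial direction and its binormal, which cannot twist.
Daughter tubes start one nominal diameter past the carina; the junction is
closed by a three-strip "pair of pants" loft (PMB end ring to the two
daughter first rings) plus two pole triangles, which is watertight by
construction. A breadth-first orientation pass makes all triangle windings
consistent and outward (positive enclosed volume), and a conservative
bounding-sphere clearance check rejects parameter combinations where the
daughter tubes would interpenetrate (small distal angles with wide,
unstenosed daughters). Post-stenosis daughter segments default to 10 local
diameters so the distal pressure-probe planes sit well inside the domain.

`measure_stenosis()` closes the loop: it slices the mesh across the lesion
window, converts each section polygon to an equivalent diameter
`2*sqrt(A/pi)` and reports `100*(1 - min/nominal)`. On the study grid the
closure error stays well under 1 % at 24–48 points per circumference.

## Boundary conditions

Two diameter-based scaling laws are exposed:

* resting flow `q = 1.43 d^2.55` (mL/min, d in mm) and hyperemic flow
  `q * CFR` with a coronary flow reserve of 3;
* the unstenosed flow split `Q_SB/Q_DMB = (d_SB/d_DMB)^2.27`, which gives
  65 %:35 % for the default daughters (34.8 % to the SB before integer
  rounding).

The imposed hyperemic inlet flow of the study conditions is **120 mL/min**,
kept as a configuration value rather than derived from the resting-flow
law: evaluating that law at d = 3.30 mm gives ~30 mL/min at rest
(~90 mL/min hyperemic), which is inconsistent with the stated 120 mL/min.
We reproduce the study as run and expose the law separately. The grid spans
splits 55:45, 65:35 and 75:25 (DMB:SB), so the side-branch flows are 54, 42
and 30 mL/min.

Blood is a shear-thinning Carreau fluid (`mu_inf` 0.0035 Pa s, `mu_0`
0.25 Pa s, `lambda` 25 s, `n` 0.25, density 1060 kg/m^3). The inlet
Reynolds number at 120 mL/min with the infinite-shear viscosity is ~234.
The reported local Reynolds number at a severe SB stenosis (~605) depends on
an unstated characteristic length and effective viscosity, so the package
does not attempt to reproduce it.

## Flow-field read-outs

Fields live in an unstructured tetrahedral container (points in mm,
velocity in m/s, pressure in mmHg). The probe planes sit **one local
diameter** proximal to the lesion start (PMB, where pressure is anchored at
the 100 mmHg mean aortic value) and one diameter distal to the lesion end
(DMB and SB). Section pressures are **area-weighted** means over the
plane/cell intersection polygons with linear in-cell interpolation —
area-weighting is robust to nonuniform sampling, and the intersection-
polygon quadrature is exact for linear fields. Pressure drops are
`100 - p_section`, and FFR is the distal-to-proximal pressure ratio
(reported at 3 decimals).

Vorticity is reconstructed per point by inverse-square-distance weighted
least squares over cell-sharing neighbors. This is exact for affine
velocity fields on any mesh (verified to 1e-10); on curved profiles the
boundary stencils are first-order biased, so quantitative vorticity checks
use interior medians plus a refinement test rather than wall values. The
helicity descriptors follow the cardiovascular-flow literature:

* **local normalized helicity** `LNH = (v . omega)/(|v||omega|)`, the
  cosine of the angle between velocity and vorticity; its sign encodes the
  handedness of rotation. Degenerate points with `|v||omega| < 1e-12` (SI)
  are set to 0, which keeps contour plots clean;
* **helicity intensity**: the volume-average of `|v . omega|` over the
  fluid domain, `(1/V) * sum_cells |v.omega| * vol`. The source study does
  not restate its normalization; this volume-averaged absolute helicity
  density is adopted here as the single authoritative definition, so
  absolute intensities from the published figures are *not* comparable and
  are never asserted.

## Synthetic fields: what they are and are not

No shipped generator solves the momentum equation. Three analytic fields
drive the tests:

* **Poiseuille** — parabolic axial profile with the analytic pressure
  gradient at `mu_inf`; LNH is identically zero (velocity is perpendicular
  to vorticity), making it the null case for helicity metrics.
* **Helical** — solid-body rotation plus axial plug, `v = (-Omega y,
  Omega x, W)`. Being affine it has machine-exact reconstruction targets:
  LNH `W/sqrt(Omega^2 r^2 + W^2)` and helicity intensity exactly
  `2 Omega W`.
* **Stenotic jet** — curved tube grids along the three branch centerlines
  with a mass-conserving axial velocity (blending toward plug flow in the
  throat), an optional post-throat swirl, and an **imposed** pressure field:
  a resistance density proportional to `(A_ref/A)^2` is integrated along
  each pathway and scaled so the drops between the probe planes equal the
  prescribed values exactly. It is a calibrated fixture — when prescribed
  with a severe case's published drops it returns that case's FFR through
  the full probe pipeline, which validates the plumbing, not the physics.
  The swirl amplitude (fraction 0.2 of the local excess axial velocity) is
  a non-physical knob that gives the jet a helical structure growing with
  severity and flow, so the study report's pressure-drop-versus-helicity
  regression has structure to summarize.

Consequently, passing tests demonstrate that the *measurement pipeline* —
probing, averaging, FFR arithmetic, helicity quadrature, fitting — is
correct against closed forms and published tabulated values. They say
nothing about jets, recirculation or transition in real coronary flow,
which require the excluded Navier-Stokes solve.

## Numerical choices

* Disc templates for field grids use ring radii inflated by
  `sqrt(2*pi/(n*sin(2*pi/n)))` so every polygon annulus carries the exact
  annulus area, and axial profiles are rescaled by a per-layer discrete
  quadrature factor so the piecewise-linear discrete flux matches the
  analytic flow. Discrete mass conservation across probe sections then
  holds to well under 0.5 % at the default 16 points per diameter (and to
  ~1e-5 on the jet fields).
* Plane probes nudge signed point distances below 1e-9 mm to one side so a
  plane coinciding with a mesh layer still yields the full section.
* The quadratic pressure-drop/flow fit has **no intercept** — a stenosis
  has zero drop at zero flow; the published coefficient pairs are
  reproduced exactly under this choice. Its RMSE uses `n - m` with m = 2
  coefficients, so the three-point per-angle fits have one residual degree
  of freedom.
* Display rounding is centralized: pressure drops at 2 decimals, FFR at 3,
  fit coefficients at 3, FFR angle differences at 2 with **exact ties
  rounded down** — the convention that reproduces every published
  difference entry (one entry sits exactly on a .xx5 tie).
* Default seeds: the synthetic generators are deterministic; only the
  noise harness (`noisy_dpq`, `simulate`) consumes randomness, preserves
  the caller's RNG state, and defaults to seed 20160805.

### Problem sizes

The shipped tests run the geometry closure at 24–48 points per
circumference with 0.5–1 mm ring spacing, field oracles at 8–18 points per
diameter, the 27-case statistics on the published table, synthetic
end-to-end runs on 1–4 case subsets at 8 points per diameter, and the
Monte-Carlo coefficient recovery at 1000 replicates — sizes chosen so the
whole suite completes in well under a minute while every tolerance above is
met with margin.

## Known limitations

* The junction loft is a template, not a solved carina shape; with wide
  unstenosed daughters at small distal angles it would self-intersect, and
  tessellation refuses those inputs rather than producing bad geometry.
* The stenotic jet imposes pressure; its velocity field is kinematic. Wall
  shear stress, transition and pulsatility are out of scope.
* The published helicity-intensity magnitudes and the R^2 = 0.80 regression
  against solver helicity depend on unpublished field data and cannot be
  reproduced; the package computes its own regression on synthetic fields
  instead.
* One main-branch FFR entry of the published 27-case table (60 % SB,
  40 degrees, 45 % split) is internally inconsistent with its printed
  pressure drop by 0.0016; the fixture keeps the printed values verbatim
  and the validation report treats that single row as a known exception.

## Reproducing the study statistics

```{r}
st <- run_study(study_config(source = "reference"))
st
```

```{r}
validate_against_reference()
```
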