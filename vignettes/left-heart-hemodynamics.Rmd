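---
title: "Systolic left-heart hemodynamics with resistive immersed valves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systolic left-heart hemodynamics with resistive immersed valves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardioriis)
```

`cardioriis` implements an image-based computational pipeline for systolic
blood flow in the left ventricle, left atrium and aortic root, comparing a
healthy mitral valve with a regurgitant (P2 posterior prolapse) valve under
two compensation patterns: an increased heart rate and a dilated ventricle.
This vignette is the package's own account of the models, the numerical
choices, and what the synthetic phantom can and cannot say about real data.

## The model

Blood is an incompressible Newtonian fluid (density $\rho = 1.06\times10^3$
kg/m$^3$, dynamic viscosity $\mu = 3.5\times10^{-3}$ Pa s) on a moving
domain $\Omega(t)$ whose wall motion is prescribed from imaging.  Each time
step solves, in order:

1. **Mesh motion.** A linear elastostatic extension of the imaged boundary
   displacement $\hat{\mathbf d}_{h,\mathrm{MRI}}$ into the volume:
   $-\nabla\cdot[2\mu_{\rm EXT}\nabla^s\hat{\mathbf d} +
   \lambda_{\rm EXT}(\nabla\cdot\hat{\mathbf d})\mathbf I] = 0$, with the
   imaged displacement on the wall, zero displacement on the atrial outlet
   (kept fixed) and zero traction on the aortic outlet.  Both Lamé-like
   parameters default to 0.4 Pa.  The extension is linear in its boundary
   data, so the six frame fields are extended once and interpolated in time.
2. **ALE velocities.** Backward differences
   $\mathbf u_{\rm ALE}^{n+1} = (\hat{\mathbf d}^{n+1}-\hat{\mathbf d}^{n})/\Delta t$
   and the wall velocity from the imaged frames.
3. **Flow.** A first-order semi-implicit ALE Navier–Stokes step: the
   convective velocity is frozen at $\mathbf u^n - \mathbf u_{\rm ALE}^{n+1}$,
   the subgrid viscosity is explicit, and viscous, pressure and valve terms
   are implicit, giving one (nonsymmetric) linear solve per step.

**Valves (RIIS).** Both valves enter the momentum equation as a resistive
penalty $\frac{R}{\varepsilon}(\mathbf u - \mathbf u_\Gamma)\,
\delta_{\Gamma,\varepsilon}(\varphi)$ supported on a layer of half-thickness
$\varepsilon$ around the immersed leaflet surface $\Gamma$, where $\varphi$
is the (unsigned) Euclidean distance to $\Gamma$ and
$\delta_{\Gamma,\varepsilon}(\varphi) = (1+\cos(\pi\varphi/\varepsilon))/
(2\varepsilon)$ for $|\varphi|\le\varepsilon$, zero outside.  Defaults:
$R = 10^4$ kg/(m s), $\varepsilon = 0.75$ mm; the prescribed leaflet
velocity is zero (the mitral valve is closed throughout systole, the aortic
valve switches between rigid open/closed templates).  The distance field
uses exact nearest-triangle queries.  The unsigned distance suffices because
the smoothed delta is even in $\varphi$.

**Turbulence.** The subgrid viscosity of the singular-value ("sigma") LES
closure, $\mu_{\rm sgs} = \rho C \Delta^2\,
\sigma_3(\sigma_1-\sigma_2)(\sigma_2-\sigma_3)/\sigma_1^2$ with
$\sigma_1\ge\sigma_2\ge\sigma_3$ the singular values of $\nabla\mathbf u^n$,
$C = 1.5$ and $\Delta$ a single global filter width equal to the average
mesh edge.  The closure vanishes identically for uniform fields, pure
shear, rigid rotation and any two-component state ($\sigma_3 = 0$); cells
with zero gradient return zero (the formula's removable singularity).

**Boundary conditions.** No-slip against the imaged wall velocity; weak
normal-traction outlets with a constant 10 mmHg atrial pressure in the
healthy scenario and synthetic elevated-V-wave / physiological aortic
waveforms (time-rescaled to the scenario's systole duration) otherwise;
null tangential velocity at the atrial outlet in the regurgitant scenarios
to control backflow instability (implemented as strong constraints, which
requires an axis-aligned outlet normal).  mmHg convert to Pa with 133.322
at the configuration boundary; the solver is SI throughout.

**Aortic valve switching.** Opening is instantaneous at the first positive
ventricle–aorta jump of area-weighted slice pressures; closing at the first
negative aortic-plane flow rate *after forward ejection has developed* —
the guard keeps sign noise during the initial pressurization transient
(null initial condition) from closing the valve at $t \approx 0$.  One open
and one close event are allowed per systole; the closure tolerance is
1 mL/s.

## Discretization and stabilization

Equal-order P1–P1 tetrahedral elements with SUPG/PSPG stabilization and a
grad-div (LSIC) term.  The stabilization parameter is
$\tau = \rho^{-1}\big[(2/\Delta t)^2 + (2|\mathbf a|/h)^2 +
(12\nu_{\rm eff}/h^2)^2 + (\sigma_r/\rho)^2\big]^{-1/2}$ with element size
$h = (6V)^{1/3}$, element-mean advection $\mathbf a$ and the RIIS reaction
$\sigma_r$ included so the stabilized form stays consistent inside the
penalty layer; the grad-div parameter is $h^2/(4\tau)$.  The linear system
is solved by BiCGSTAB with an incomplete-LU preconditioner that is reused
across steps and refreshed when the iteration count degrades, with a sparse
direct fallback.  The relative tolerance is $10^{-8}$.

Three numerical choices deserve emphasis, because they are where an
under-resolved immersed valve bites:

* **Layer width vs. mesh.** The physical $\varepsilon = 0.75$ mm is far
  below a desk-scale mesh size.  The layer half-width used by the solver is
  `max(eps, 1.2 x mean shortest edge near the valve)` while the penalty
  prefactor keeps the physical $R/\varepsilon$; since the across-layer
  integral of $\delta$ is one, the physical leak velocity
  $\Delta p\,\varepsilon/R$ is unchanged.  The mesh is locally refined in
  the axial direction around both valves for this reason (the reference
  study refines to 0.35–0.4 mm near the valve on a cluster).
* **Grad-div boost in the layer.** The transvalvular pressure jump
  (tens of mmHg across one or two cells) spuriously accelerates fluid at
  the fringe of the smoothed layer.  Cells inside the layer get a
  reaction-strengthened grad-div parameter, which suppresses this
  circulation; cells near a reconstructed regurgitant orifice are exempted
  (using the orifice location known from the valve reconstruction) so the
  channel still conducts.
* **Enclosed-flow gauge.** With no stress boundary anywhere (both valves
  closed and no outlet), the pressure is defined only up to a constant —
  the same degeneracy that forces the healthy scenario to start just after
  the aortic valve opening.  `ns_step()` pins one pressure degree of
  freedom in that case.

An experimental sharp-limit variant of the valve term (surface quadrature
of the collapsed layer, `riis_surface_quadrature()`, with an optional
tangent-plane projection of the PSPG gradients) is exported for channel
experiments; the scenario pipeline uses the smoothed nodal form above,
which proved markedly more robust on coarse meshes.

## The phantom and what it emulates

No patient data are distributed; every pipeline input is synthesized by the
phantom with known ground truth:

* **Geometry.** Ventricle: lower half of a prolate ellipsoid (semi-axes
  24, 24, 52 mm) truncated at the basal plane; closed-form cavity volume.
  The basal disc splits into two mouths: an atrial tube that morphs from
  the half-disc section to circular sections, bulges, and ends at a flat
  atrial outlet; and a gently bent aortic tube.  The tubes are analytic
  swept surfaces (star-shaped cross-sections), so the phantom has an exact
  inside/outside test and quadrature volume oracles; a true spherical-cap
  atrium cannot be attached conformingly to a shared tetrahedral base disc
  without an unstructured mesher, so the dome-ended tube stands in for it.
  Dilation scales everything about the cavity centroid.
* **Motion.** Six frames from end diastole to end systole, referenced to
  end systole (frame six is zero).  The contraction field is analytic —
  radial plus longitudinal shortening in the ventricle, blended to zero up
  the tubes and vanishing at the atrial outlet — with the amplitude solved
  by 1-D root finding so the swept volume matches the target stroke volume
  (92 mL before dilation; the dilated scenario also dilates the
  displacement field, scaling the swept volume by $1.25^3$).  The cosine
  time profile makes the cavity volume decrease monotonically.
* **Images.** Short-axis stacks (15 slices of 8 mm thickness/spacing, 1 mm
  in-plane) and two orthogonal long-axis single slices; voxel values are
  partial-volume fractions of the cavity interior computed by sub-sampling
  the analytic indicator under the inverse of the motion map.
* **Valve traces.** 18 radial planes, 10 degrees apart, through the annulus
  center; on each plane one anterior and one posterior leaflet profile of
  32 points from annulus to free margin.  The closed valve is a dome over
  the annulus with a coaptation crease through the posterior half; healthy
  traces share the last profile point per plane exactly.  The P2 prolapse
  everts the mid-posterior segment (sector half-width 45 degrees) toward
  the atrium, flail-like, with the bump amplitude solved so the
  margin-to-margin strip area equals the requested orifice area (default
  40 mm^2, a clinically severe effective regurgitant orifice; dilation
  scales it by the factor squared).  Trace noise is isotropic Gaussian,
  default 0.3 mm, mimicking manual tracing at ~1.25 mm resolution.

What passing phantom tests do **not** show: patient anatomy (no papillary
muscles, no atrial appendage, idealized tubes), registration errors (the
phantom supplies displacements directly), image segmentation (out of
scope), and the paper-scale resolution — see "Problem sizes" below.

## Valve reconstruction choices

The tracing protocol fixes the counts (1152 = 32 samples x 36 profiles raw
points; 32,000 = 1000 x 32 ring-resampled points) but not the fitting
details; the package's choices:

* Ring curves are fitted per coordinate by periodic cubic smoothing
  B-splines over a uniform parameter (one knot interval per point), which
  stays well conditioned for arbitrarily clustered points — the free-margin
  ring of a coapting valve contains 18 exactly duplicated point pairs.  A
  tiny curvature-penalty floor ($10^{-8}$) keeps that degenerate case
  solvable; the smoothing weight follows the fixed rule
  $\lambda = n\,\sigma^2/\bar\ell^2$ with $\sigma$ the trace noise and
  $\bar\ell$ the mean chord, so noiseless rings are interpolated.
* How the two leaflets' profiles interleave into a ring traversal is not
  dictated by the protocol.  Near the annulus a ring is an azimuthal
  circle; near the free margin of a coapting valve it degenerates into the
  coaptation arc traversed once per leaflet.  Each ring picks, between the
  two canonical family orderings (anterior block forward or reversed), the
  shorter closed polygon, and consecutive resampled rings are cyclically
  aligned.
* The immersed membrane itself is built per leaflet (an inner fan from the
  valve center out to the annulus or the coaptation crease, plus a
  posterior sector sheet welded along the crease), which keeps the
  coaptation seam and any regurgitant window topologically exact.  A
  ring-grid surface (`build_surface()`) remains available for single-sheet
  clouds; on the fully coapting doubled-sheet valve its structured grid
  cannot equalize anterior and posterior profile spans, so its edge-length
  coefficient of variation (~0.39) exceeds the 0.3 reached on single-sheet
  shapes; the optional projected-smoothing relaxation is off by default
  because closest-point projection can hop between coapting sheets.
* The annulus is warped onto the wall by harmonically extending the
  closest-point gap over the surface (combinatorial Laplacian, discrete
  maximum principle), and the membrane is extended slightly past the
  annulus ("skirt") so the rim cannot leak between the polyline annulus
  and the faceted wall.

## Scenarios, indices, and reporting rules

* H: healthy valve, 75 1/min, $T_S = 0.32$ s, aortic valve open at $t=0$
  (the simulation starts just after opening; the isovolumic phase of a
  fully sealed chamber has no pressure gauge).
* R1: P2 prolapse, 90 1/min, $T_S = 0.26$ s, both valves closed at $t=0$
  (the regurgitant orifice provides the stress boundary), elevated-V-wave
  atrial pressure, null-tangential atrial outlet.
* R2: the R1 valve, geometry and displacement dilated by 1.25, at 75 1/min.
  The systole duration of the dilated scenario is not separately specified
  by the shared motion protocol; the package keeps 0.32 s, consistent with
  its 75 1/min heart rate.

Indices: $SV = \int Q_{\rm LVOT}\,dt$; $RV = \int Q_{\rm MV}^{+}\,dt$
(atrium-directed mitral flow only, so bidirectional closed-valve leakage
does not accumulate); $CO = SV \cdot HR/1000$;
$RF = 100\,RV/(SV+RV)$.  An RV below 3% of the total ejected volume is
indistinguishable from numerical closed-valve leakage (the reference
preprocessing comparison puts that leakage near 1.2%), so RF is reported as
0 in that case.  The atrial turbulence ratio and atrial-wall WSS summaries
are evaluated over the anatomical atrium — atrial-region cells above the
mitral annulus plane — because the tube segment below the valve belongs
hemodynamically to the ventricle during systole.  Valve WSS uses the
resolved velocity gradient interpolated at leaflet-triangle centroids with
the leaflet's own normals and $\mu_{\rm eff} = \mu + \mu_{\rm sgs}$.

## Problem sizes

The reference computations use ~1.5 mm meshes with 0.4 mm valve refinement
and $\Delta t = 2.5\times10^{-4}$ s on a cluster; the package's defaults are
a desk-scale counterpart chosen to finish a scenario in minutes on one CPU:
a ~7,000-node tetrahedral mesh (butterfly-disc parameter 6, axially refined
around both valves) and $\Delta t$ between 2.5 and 4 ms.  At this scale the
regurgitant orifice spans only a few cells, so the reported regurgitant
fractions are smaller than at patient resolution and only the *orderings*
between scenarios (healthy RF of zero after the leak threshold, positive RF
and delayed aortic opening in the regurgitant scenarios, higher atrial
turbulence ratios than the healthy floor) are meaningful — which is exactly
what the scaled-down acceptance runs assert.

```{r example}
cfg <- scenario_config("R1")
rep <- run_scenario(cfg)
rep$rf_pct      # regurgitant fraction (%)
rep$t_o         # delayed aortic valve opening (s)
```

## Known limitations

* The phantom LVOT flow includes the squeeze of the contracting aortic
  root (the motion blend contracts the near tube segments), so the
  LVOT-integrated stroke volume slightly exceeds the transvalvular volume.
* The null-tangential outlet constraint requires an axis-aligned outlet.
* Steady verification problems should be run at creeping-flow parameters;
  at physiological Reynolds numbers a 40 mm pipe is entirely entrance
  region and Poiseuille theory does not apply.
* Single cycle, systole only, no diastole and no fluid–structure
  interaction of the leaflets.
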