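---
title: "Electro-thermal modeling of RF ablation lesions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electro-thermal modeling of RF ablation lesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rfablate simulates radiofrequency catheter ablation on the two preclinical
lesion-assessment models — beating heart (BH, myocardium under a deep blood
pool) and thigh muscle (TM, striated muscle under a 20 mm blood layer with
an air interface) — plus an *intermediate* model that pairs the TM geometry
with myocardium properties to separate geometric from material effects.
This vignette records the model equations, the numerical scheme, the
parameter defaults and why they are what they are, what the verification
fixtures do and do not establish, and the design decisions that were
genuinely open.

## Governing equations and assumptions

At 500 kHz the tissue is resistive on the centimeter scale, so the
electrical problem is quasi-static: $\nabla\cdot(\sigma(T)\nabla\Phi)=0$,
with Joule heating $Q_{RF}=\sigma|\nabla\Phi|^2$. The thermal problem is
the bioheat equation without perfusion and metabolic terms (both are
negligible on ablation time scales relative to $Q_{RF}$; capillary
perfusion differences between the tissues are a known limitation, see
below), written as an enthalpy balance
$\partial h_t/\partial t = \nabla\cdot(k\nabla T) + Q_{RF}$ so that
vaporization can be represented without tracking steam:

* below 99 °C the volumetric enthalpy slope is $\rho c$;
* between 99 and 100 °C it is $H_t/\Delta T$ with $\Delta T = 1\,$°C and
  $H_t = H_w C$, where $H_w = 2256\,\mathrm{kJ/kg}\times
  958\,\mathrm{kg/m^3} = 2.161\times10^9\,\mathrm{J/m^3}$ is the
  volumetric latent heat of water at 100 °C and $C$ the tissue water mass
  fraction (0.737 myocardium, 0.795 striated muscle);
* above 100 °C the dehydrated $\rho c$ is taken identical to the hydrated
  one (modeling distinct dehydrated properties moves lesion sizes by
  hundredths of a millimeter).

The sensible branch is extended below 37 °C so the 25 °C irrigation
boundary is representable. Electrical conductivity rises linearly by
1.5 %/°C from its 37 °C reference — the simplest reading of a %/°C
specification and the standard choice in RF ablation modeling — and
collapses by two orders of magnitude across 99–101 °C; the collapse shape
is not prescribed by measurements, so it is log-linear: smooth, monotone
and bounded. Blood conductivity (0.748 S/m) is constant because blood
temperature is never solved; whether blood should also receive a
temperature coefficient is genuinely ambiguous, but since the blood pool
stays near 37 °C except in a thin boundary layer the effect is second
order.

Damage uses first-order Arrhenius kinetics,
$\Omega(t)=\int_0^t A e^{-E_a/(R\,T(\tau))}d\tau$ with
$A=7.39\times10^{39}\,\mathrm{s^{-1}}$,
$E_a=2.577\times10^5\,\mathrm{J/mol}$ — one parameter pair for both
tissues, which places the constant-exposure $\Omega=1$ point near 58–60 °C
at 5 s, consistent with the 72 °C/5 s and 55 °C/60 s isotherm rules of
thumb. The $\Omega\ge1$ region is the lesion; depth is measured from the
undisturbed tissue plane (not the electrode tip), maximum width is the
largest horizontal diameter at any depth, and volumes are full-lesion
(axisymmetric revolution, doubled half-domain).

## Geometry and meshing

The catheter is a 7.5 Fr (2.5 mm at 1 Fr = 1/3 mm) electrode, 3.5 mm long,
modeled as a 2.25 mm cylinder with a 1.25 mm hemispherical tip — the tip
shape is not prescribed anywhere, hemispherical is the standard
irrigated-tip idealization — followed by a polyurethane shaft four
electrode diameters long (the modeled shaft length is likewise an open
choice; beyond a few diameters it only adds blood-cooled surface).
Insertion depths of 0.5 mm (90°), 0.498 mm (45°) and 0.193 mm (0°)
equalize the electrode-tissue contact area across orientations;
`electrode_contact_area()` verifies this by direct surface quadrature
rather than re-deriving the depths. The tissue surface stays flat
(no mechanical deformation), the domain extends 40 mm around the
electrode, and distant boundaries carry the dispersive 0 V condition; the
TM/intermediate blood layer is 20 mm high by default with a zero-current
air interface on top.

Meshes are graded structured grids — triangles in the meridian plane for
the perpendicular catheter (the configuration is a solid of revolution up
to the far-field box, whose influence is screened by the 0 V boundary),
tetrahedra on the $y\ge0$ half-domain for tilted catheters. Default
spacing is 0.14 mm at the electrode, 0.3 mm across the expected lesion
zone, growing geometrically to 5 mm in the far field (about 3,800 nodes
axisymmetric). Region classification is by element centroid against the
analytic capsule, which staircases the curved electrode surface at the
local cell size; the mesh-consistency tests bound the resulting volume
error. `convergence_study()` implements the harness that accepts the
coarsest resolution whose lesion depth moves less than 0.5 mm and peak
temperature less than 1 °C against the next refinement — the same
criteria used to fix the defaults.

## Numerical scheme

One time step (default 50 ms, within the 20–100 ms range validated by the
convergence criteria) consists of:

1. an electrical solve with element conductivities from the current
   temperature; the linear problem is solved once at unit electrode
   voltage and rescaled by $\sqrt{P_\mathrm{applied}/P_\mathrm{unit}}$,
   which enforces constant applied power exactly at frozen conductivity
   (no feedback iteration needed);
2. a backward-Euler thermal step with mass-lumped capacity, Robin
   (convective) conditions on blood-facing interfaces, Dirichlet data at
   the irrigated electrode zone (25 °C) and outer tissue contours (37 °C).
   The capacity is the *enthalpy secant* between the previous temperature
   and the current Picard iterate, so the energy deposited while a node
   crosses the 99–100 °C band equals the latent heat exactly — nodes
   cannot jump the band. Picard iteration stops when the largest nodal
   change is below 0.1 °C (cap 10); outside the latent band the operator
   is linear and the cached factorization is reused without refactoring.

Applied powers are 80% of the nominal setting (the torso outside the
40 mm domain is not modeled, and the dispersive-patch path it represents
absorbs about a fifth of the power). The discrete energy ledger —
deposited RF energy, stored enthalpy, convective and Dirichlet boundary
losses — closes to machine precision on the lumped scheme, and the test
suite requires closure within 1%.

Damage accumulates by trapezoidal quadrature on the solver time grid
(second order, matching the stepping granularity); for constant
temperatures the rule is exact, which the tests exploit by checking
against the closed form to six digits.

## Verification strategy

No external data enters the package, so every stage is checked against a
self-contained reference (`verify_analytic()` runs them all):

* **Concentric spheres**: conductance $4\pi\sigma/(1/r_1-1/r_2)$,
  $r^{-4}$ dissipation profile and exact power normalization exercise the
  electrical assembly, Dirichlet handling and power control (within 1%).
* **Conduction slab**: a Robin-surface step response against the
  eigenfunction series (12 terms), plus the lumped-capacitance limit at
  small Biot number, exercise the transient thermal stepping (within
  0.5 °C / 1%).
* **Damage oracles**: constant exposures (closed form) and a linear ramp
  (adaptive quadrature) pin the Arrhenius integration.

These fixtures emulate the physics pieces, not real measurements: passing
them shows the discretization solves the stated equations, not that the
equations capture everything in vivo (no steam dynamics, no tissue
deformation, no perfusion, one Arrhenius pair for both tissues — all
outside scope).

## Study conditions and problem sizes

The study matrix is 3 models × 3 energy settings (25 W/20 s, 50 W/6 s,
90 W/4 s) × 3 orientations, observed to 90 s. Perpendicular scenarios run
axisymmetric at the default resolution with 50 ms steps — each full 90 s
scenario takes tens of seconds on one CPU. Tilted-catheter (0°/45°) runs
use the half-domain tetrahedral mode at several-fold coarser spacing
(roughly 15–25 thousand nodes, 100 ms steps), a deliberate desk-scale
choice: at that density the absolute lesion sizes carry a few tenths of a
millimeter of discretization error, so the associated checks assert the
robust features — the thigh-vs-heart ordering and the high-power
width/depth ratio — rather than numeric equality. The anisotropy study
(isotropic $k=0.56$ vs $\mathrm{diag}(0.633, 0.487, 0.487)$ W/m·K with
fibers along one surface-parallel axis; the mean is kept at the isotropic
value) requires the 3-D mode because fiber anisotropy breaks axial
symmetry; it runs both members on the same mesh so discretization bias
cancels in the deltas. The depth, transverse-width and volume deltas are
resolution-robust; the fiber-direction width surplus, a one- to
few-tenths-of-a-millimeter quantity read off a max-extent contour on
cells of comparable size, carries discretization noise of the same order
at this density, so only its sign and its confinement to the fiber
direction are treated as reliable at desk scale.

## Design decisions that were genuinely open

* Whether the buried part of the hemispherical tip feels irrigation: the
  irrigated 25 °C zone is the cylindrical part only; buried tip facets
  are plain conduction interfaces, and tip facets in blood get the
  electrode-blood film coefficient.
* Shaft-blood facets use the electrode-blood film coefficient (both are
  catheter surfaces washed by the same flow).
* Irrigation stays active through the 90 s observation window.
* The anisotropic tensor orients the *longitudinal* (higher) conductivity
  along a single fiber axis parallel to the surface — the configuration
  that can produce a fiber-direction width surplus with an unchanged
  transverse width; orienting it isotropically in the surface plane could
  not.
* The BH blood pool extends to the domain boundary; its exact height is
  immaterial once the 0 V far field dominates (the blood-height sweep
  shows the TM plateau above 10 mm).
* Between-model comparisons (TM vs BH vs intermediate) reuse identical
  tissue-region discretizations so the reported deltas are free of
  meshing bias.

## Known limitations

Steam-pop dynamics have no validated model and are excluded — the
conductivity collapse plus latent heat is adequate for lesion sizing but
says nothing about pop incidence. Tissue mechanical deformation and
contact-force effects, heartbeat-induced catheter motion, capillary
perfusion (which differs strongly between myocardium and striated muscle
and would deepen the gap between the models at long pulses), electrical
anisotropy, and frequency dispersion beyond the single 500 kHz operating
point are all out of scope. Lesion metrics at the coarse tetrahedral
resolutions are ordering-accurate, not size-accurate.
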