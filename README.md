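# rfablate

Coupled electro-thermal finite-element simulation of irrigated-tip
radiofrequency (RF) catheter ablation, built to compare the two in-vivo
preclinical models used to assess ablation catheters: the **beating-heart
(BH)** model, where the catheter is applied to myocardium inside the blood
pool of a cardiac chamber, and the **thigh-muscle (TM)** model, where it is
applied to exposed striated muscle under a blood-filled skin cradle with an
air interface 20 mm above the tissue. Experimentally the TM model produces
slightly larger lesions; the package quantifies how much of that difference
is explained by tissue properties (chiefly the higher electrical
conductivity of striated muscle, 0.446 vs 0.281 S/m) and how much by the
altered geometry, via an *intermediate* model (TM geometry, myocardium
properties), a blood-height sweep and a thermal-anisotropy study.

## Model

* **Electrical problem** (quasi-static, 500 kHz): `div(sigma(T) grad Phi) = 0`
  with the RF source `Q_RF = sigma |grad Phi|^2`. Tissue conductivity rises
  1.5 %/°C from its 37 °C value and collapses two orders of magnitude
  between 99 and 101 °C (dehydration). The electrode is an equipotential
  surface whose voltage is rescaled every time step to hold the applied
  power constant (25 W/20 s, 50 W/6 s or 90 W/4 s nominal, applied at 80%
  because the torso is not modeled); 0 V on the distant boundaries stands in
  for the dispersive patch, and the TM air-blood surface carries zero
  current.
* **Thermal problem**: enthalpy form of the bioheat equation
  `dh/dt = div(k grad T) + Q_RF` with an apparent heat capacity that equals
  `rho c` outside the 99-100 °C band and `H_t / 1 °C` inside it, where
  `H_t = 2.161e9 J/m^3 x` (tissue water fraction) is the vaporization latent
  heat. Blood is not solved thermally: electrode-blood and tissue-blood
  interfaces carry convective conditions (h = 3310 and 694 W/m²K, blood at
  37 °C), saline irrigation pins the cylindrical electrode zone at 25 °C,
  and the outer tissue contours stay at body temperature.
* **Lesion**: the Arrhenius damage index
  `Omega(t) = Int A exp(-Ea/(R T(tau))) dtau` (A = 7.39e39 1/s,
  Ea = 2.577e5 J/mol, T in kelvin); the `Omega = 1` contour (63% cell
  death) is the lesion boundary, reported as maximum depth, maximum width,
  their ratio, and volume, at the end of the RF pulse and at 90 s (thermal
  latency). `P_T`/`E_T` are the percentages of applied power (at onset) and
  delivered energy (at pulse end) dissipated in the tissue rather than the
  blood.

The perpendicular-catheter scenarios run on a graded axisymmetric
triangular mesh (the geometry is a solid of revolution); the 45° and
parallel orientations and the fiber-anisotropy study run on a graded
half-domain tetrahedral mesh. Assembly is linear (P1) with mass lumping,
backward-Euler time stepping, Picard iteration on the nonlinear
coefficients, and an enthalpy-secant capacity so no node can jump the
latent band without paying its latent heat. Sparse systems are solved with
supernodal Cholesky factorizations (Matrix/CHOLMOD).

## Worked example

```r
library(rfablate)

scenario <- scenario_geometry("BH", orientation = 90)
mesh <- build_geometry(scenario, mesh_resolution())
run <- run_simulation(mesh, energy_setting(25, 20),
                      snapshot_times = c(20, 90))
print(lesion_at(run, 20))
print(lesion_at(run, 90))
print(run)
```

prints (about 20 s on one CPU, ~3,800 mesh nodes):

```
<lesion_metrics> depth 3.44 mm, width 6.45 mm, ratio 1.87, volume 78.6 mm3
<lesion_metrics> depth 3.88 mm, width 6.77 mm, ratio 1.74, volume 100.4 mm3
<rf_run> BH 90 deg, 25 W/20 s (applied 20 W)
  P_T = 16.02%, E_T = 18.19%, max T = 90.4 C
```

i.e. a 25 W/20 s beating-heart lesion 3.44 mm deep and 6.45 mm wide at
power-off that keeps growing to 3.88 x 6.77 mm by 90 s, with 16% of the RF
power entering the tissue at onset (the rest is lost to the blood pool).
The same call with `scenario_geometry("TM")` gives the thigh-muscle lesion
(4.17 -> 4.90 mm deep), about 1 mm deeper at this setting — the headline
difference between the two preclinical models.

The command-line front end wraps the same functions:

```sh
exec/rfablate run --model TM --power 50 --duration 6
exec/rfablate matrix --out results/       # full 3 models x 3 settings x 3 angles
exec/rfablate sweep --heights 5,10,15,20  # blood-pool height study
exec/rfablate verify                      # closed-form benchmark report
```

## Package layout

| | |
|---|---|
| `R/materials.R` | material library, sigma(T), enthalpy/apparent capacity, conductivity tensor |
| `R/geometry.R`, `R/mesh.R` | scenario geometry, graded meshes, region/boundary tags, VTK export |
| `R/fem.R`, `R/solver.R` | P1 assembly, electrical solve with power control, implicit thermal stepping, full runs |
| `R/analysis.R` | Arrhenius damage, lesion metrics, isotherms, power/energy accounting |
| `R/experiments.R` | study matrix, blood-height sweep, anisotropy study, convergence harness |
| `R/verification.R` | closed-form benchmark cases (slab, concentric spheres, damage oracles) |

The methods vignette (`vignettes/rfablate-methods.Rmd`) documents the
governing equations, numerical choices, verification strategy and known
limitations.
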