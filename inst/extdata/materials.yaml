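# Material library: electrical conductivity sigma (S/m, at 500 kHz and 37 C),
# thermal conductivity k (W/m.K), density rho (kg/m3), specific heat c
# (J/kg.K), water mass fraction (dimensionless). Blood is only present in the
# electrical problem, so it carries no thermal fields.
materials:
  - name: myocardium
    kind: tissue
    sigma: 0.281
    k: 0.56
    rho: 1081.0
    c: 3686.0
    water_mass_fraction: 0.737
    k_transverse: 0.487
    k_longitudinal: 0.633
  - name: striated_muscle
    kind: tissue
    sigma: 0.446
    k: 0.49
    rho: 1090.0
    c: 3421.0
    water_mass_fraction: 0.795
  - name: blood
    kind: blood
    sigma: 0.748
  - name: electrode_ptir
    kind: electrode
    sigma: 4.6e+6
    k: 71.0
    rho: 21500.0
    c: 132.0
  - name: catheter_polyurethane
    kind: shaft
    sigma: 1.0e-5
    k: 0.023
    rho: 1440.0
    c: 1050.0
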