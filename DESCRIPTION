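Package: rfablate
Title: Electro-Thermal Finite-Element Simulation of Radiofrequency Ablation Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled quasi-static electrical and transient bioheat simulation of
    irrigated-tip radiofrequency catheter ablation on unstructured meshes.
    Implements the enthalpy (apparent heat capacity) formulation of the bioheat
    equation with water-vaporization latent heat, temperature-dependent
    electrical conductivity with a two-decade collapse near 100 degrees C,
    constant-power control, Arrhenius thermal damage accumulation and lesion
    geometry metrics (depth, maximum width, volume). Ships the beating-heart,
    thigh-muscle and intermediate preclinical model geometries with
    perpendicular, 45-degree and parallel catheter orientations (axisymmetric
    and half-domain tetrahedral modes), power/energy accounting between tissue
    and blood, a mesh-convergence harness, blood-height and thermal-anisotropy
    studies, and closed-form verification benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
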