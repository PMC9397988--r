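Package: patraction
Title: Finite-Element Simulation of Posteroanterior Lumbar Spinal Traction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational model of posteroanterior (PA) lumbar
    traction delivered by the roller actuator of an automated massage bed.
    Builds a parametric multi-tissue mid-sagittal lumbar phantom (nine tissue
    classes, BMI-dependent subcutaneous fat), meshes it with quadratic
    triangles, solves quasi-static plane-strain linear elasticity with
    frictionless contact against displacement-driven rigid rollers and a
    deformable bed mat, and summarises per-disc von Mises stress and
    equivalent strain across traction levels and BMI classes, including
    load-shielding comparisons and safety-threshold checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
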