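Package: trabeflow
Title: Mechanical Microenvironment of Perfused Trabecular-Bone Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mechanical environment sensed by cells seeded in
    decellularized trabecular-bone scaffolds cultured in a perfusion
    bioreactor. Provides a synthetic trabecular microstructure generator
    calibrated to measured bone morphometry (porosity, trabecular thickness,
    pore-size distribution), 3D voxel morphometry (local thickness, inscribed
    sphere pore sampling), Darcy-law permeability calibration from measured
    differential pressure, a reduced-order porous-medium model of the
    bioreactor cartridge, and a pore-scale creeping-flow (Stokes) solver on
    voxelized geometry with wall-shear-stress extraction. Small scalar
    characterizations (compressive elastic modulus by stress-strain
    regression, EDS Ca/P weight ratio) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
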