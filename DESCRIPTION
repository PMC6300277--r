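Package: shadewalk
Title: Gridded Simulation of Ground-Level Shade and Incident Solar Energy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic, spatially distributed simulation of ground-level
    shade fraction and incident solar energy across heterogeneous landscapes.
    Combines per-timestep solar geometry and clear-sky irradiance with a
    cell-marching walking algorithm that traces a ray from every ground cell
    toward the sun, accumulating light-transmittance losses through vegetation
    voxels and detecting terrain interception. Includes co-registered raster
    stacks read from ESRI ASCII Grid files, temporal aggregation of shade and
    energy outputs, a three-parameter calibration workflow against observed
    irradiance series, synthetic landscape generators, and an independent
    fine-step ray-march oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
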