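Package: stenoflow
Title: Pressure Drop, FFR and Helical Flow Analysis of Stenosed Coronary Bifurcations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational study of how the distal bifurcation angle of a
    stenosed coronary bifurcation modulates side-branch pressure drop and fractional
    flow reserve (FFR). Builds parametric LAD-first-diagonal bifurcation lumens
    (centerlines on a sphere, Finet-law diameters, eccentric raised-cosine stenoses),
    applies diameter-based scaling laws for boundary conditions (resting flow,
    hyperemic flow, flow split, Carreau rheology, Reynolds number), post-processes
    unstructured flow fields for section pressures, pressure drops, FFR, vorticity,
    local normalized helicity and helicity intensity, and fits the through-origin
    quadratic pressure-drop/flow relation with RMSE diagnostics. Synthetic analytic
    flow fields with closed-form helicity stand in for an external CFD solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
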