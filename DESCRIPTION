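Package: occlusim
Title: Lattice-Boltzmann / Discrete-Element Simulation of Thrombotic
    Occlusion in Tortuous Arterioles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coupled two-dimensional lattice-Boltzmann (D2Q9 BGK) and
    discrete-element simulation of platelet-driven thrombus formation and
    occlusion in tortuous arterioles. Builds cosine-centerline microvessel
    geometries, solves pressure-driven plasma flow with half-way bounce-back
    walls, transports rigid spherical platelets with Stokes drag, soft-sphere
    contact, spring adhesion and fluid torque, activates platelets above a
    critical shear stress or on contact with activated platelets, and feeds
    the platelet reaction forces back onto the fluid so that growing thrombi
    reduce the flow rate. Includes a plane-Poiseuille validation harness,
    tortuosity and platelet-size scenario presets, and CSV/VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
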