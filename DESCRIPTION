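Package: nemshell
Title: Equilibrium Shapes and In-Plane Nematic Ordering of Closed Flexible Shells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled minimization of membrane shape and in-plane nematic
    order for closed axisymmetric shells (vesicles, liquid-crystal shells)
    covered by curved rod-like molecules such as BAR-domain proteins or
    bent-core mesogens.  The free energy combines Helfrich spontaneous-
    curvature bending, a Landau-de Gennes condensation and intrinsic elastic
    energy for a surface Q-tensor, and a deviatoric term coupling the
    molecules' intrinsic curvature to the local normal curvature through the
    Euler relation.  Shapes are parameterized by a Fourier series for the
    tangent angle of the profile curve and relaxed at fixed surface area and
    reduced volume; textures are relaxed by annealed Metropolis Monte Carlo.
    Includes topological-defect detection with half-integer winding numbers,
    shape classification (oblate, stomatocyte, prolate, phi-shape, necklace),
    multi-start branch comparison, synthetic seed-shape and defect-texture
    generators, and CSV/JSON/VTK export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
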