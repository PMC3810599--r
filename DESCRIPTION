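Package: tetvolt
Title: Membrane Potential on Tetrahedral Meshes with Stochastic Channel
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Vertex-centered finite-volume solver for the quasi-static
    electrical potential on unstructured tetrahedral meshes, coupled to
    membrane channel kinetics.  The cytoplasm is treated as a purely
    resistive medium (Laplace equation) and the membrane as a distributed
    capacitor, discretised with median-dual control volumes around each
    mesh vertex and advanced by backward Euler on a banded linear system.
    Matrix bandwidth is minimised by principal-axis or breadth-first /
    Cuthill-McKee vertex reordering.  Channels are Markov state models
    with voltage-dependent transition rates; single-channel currents may
    be Ohmic or Goldman-Hodgkin-Katz (GHK) with discrete stochastic ion
    transport, simulated exactly with the Gillespie direct method and
    coupled to the field solve through an adaptive communication step.
    Includes TetGen and Gmsh mesh readers, structured cylinder and
    branched-dendrite mesh generators, and the Rallpack benchmark suite
    with analytic passive-cable references.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    jsonlite
Depends:
    R (>= 4.0)
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
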