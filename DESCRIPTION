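Package: trensh
Title: Electrical-Network Simulation of Brain AVM Hemodynamics and
    Transvenous Retrograde Embolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady-state blood flow through stochastic brain
    arteriovenous malformation (AVM) networks using the electrical-circuit
    analogy of Hagen-Poiseuille flow (Kirchhoff node and cycle laws solved as
    a sparse nodal-potential system with batched right-hand sides). Generates
    compartmentalized plexiform nidus architectures with an intranidal
    fistula, enumerates pressure-set scenario grids (controlled systemic
    hypotension, central venous pressure elevation, temporary balloon
    occlusion of arterial feeders, draining-vein retrograde injection,
    cardiac-phase timing), and quantifies transvenous retrograde nidus
    sclerotherapy under controlled hypotension (TRENSH) manoeuvres through
    reachability-based sclerosant filling, total nidal flow, and a normalized
    rupture-risk statistic. Includes batch experiment runners with the
    accompanying statistics, JSON/GraphML serialization, CSV export, and
    frame-by-frame animation of simulated treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
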