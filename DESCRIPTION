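Package: afpice
Title: Ice Nucleation Analysis Near Antifreeze Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for atomistic simulations of heterogeneous ice
    nucleation near antifreeze proteins. Classifies water molecules into
    hexagonal, cubic and interfacial ice via Steinhardt bond-order
    correlations, tracks the largest ice nucleus through a trajectory,
    estimates critical nucleus sizes by the seeding method, computes
    hydrogen-bond lifetime and residence correlation functions, measures
    interfacial order profiles (density maps, dipole distributions, layer-wise
    q6), quantifies the lattice match between an ice-binding site's hydroxyl
    array and the ice basal plane, and evaluates classical-nucleation-theory
    free-energy barriers with a line-tension term. Includes generators for
    synthetic reference systems (proton-disordered ice Ih/Ic lattices, liquid
    boxes, embedded nuclei, channel-water chains, stochastic nucleus-size
    series and hydrogen-bond event series) and readers/writers for GRO, PDB
    and XYZ structure formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
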