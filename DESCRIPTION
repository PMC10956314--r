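Package: vox4d
Title: Hybrid Lattice/Particle Spatial Stochastic Simulation of Cellular
    Reaction-Diffusion Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A spatial-stochastic simulation engine for cellular pathways
    combining deterministic finite-difference diffusion of bulk (small
    molecule) concentrations on a cubic voxel lattice with off-lattice
    Brownian dynamics of individually tracked point particles. Supports
    compartments with species-level accessibility rules, 2-D membrane
    diffusion, membrane microdomain (lipid raft) partitioning, unimolecular
    and bimolecular reactions (particle-particle kinetics via
    Andrews-Bray-adjusted Smoluchowski binding radii), probabilistic
    inter-compartment transport, concentration sources and sinks, and
    reversible particle immobilization. Models are described by S4 objects
    with an XML serialization dialect; built-in model generators cover
    cooperative calcium-calmodulin activation, calcium microdomain
    gradients, and CEACAM1 lipid-raft clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
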