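Package: delfrag
Title: Deep Evolutionary Learning for Multi-Objective Molecular Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fragment-based deep evolutionary learning for de novo drug
    design.  Molecules are represented as BRICS fragment sequences and
    junction trees, modelled with a property-regularized variational
    autoencoder, and optimized in the latent space by a multi-objective
    evolutionary loop (non-dominated sorting, crowding distance,
    tournament selection, uniform crossover, Gaussian mutation) against
    synthetic accessibility, lipophilicity and protein-ligand binding
    affinity.  Includes population quality metrics (validity, novelty,
    uniqueness, 1-Wasserstein distance, Pareto hypervolume), a docking
    adapter for AutoDock-Vina-compatible engines with a deterministic
    surrogate for engine-free runs, and virtual screening of first-front
    molecules.  Primitive chemistry is delegated to RDKit through a
    batched Python subprocess bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
SystemRequirements: Python (>= 3.8) with RDKit, on the PATH; Open Babel
    (obabel) and an AutoDock-Vina-compatible engine only for physical
    docking.
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
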