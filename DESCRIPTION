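Package: icvae
Title: Interpretable Conditional Variational Autoencoder for De Novo
    Molecular Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Property-conditioned generation of drug-like molecules from
    SMILES strings with an interpretable latent space. A convolutional
    conditional variational autoencoder is trained with a shifted-mean
    Gaussian prior: each conditioned molecular property (molecular weight,
    logP, hydrogen-bond acceptor/donor counts, TPSA, QED, synthetic
    accessibility) is scaled onto a [0, 500] label range and used as the
    prior mean of its own latent coordinate, so latent coordinates read
    property values out linearly and molecules with target properties are
    generated by setting latent coordinates directly. Includes SMILES
    tokenization and one-hot coding, seeded training with loss logging,
    controlled generation and property-grid sweeps, latent-linearity
    diagnostics, generation metrics (validity, uniqueness, novelty,
    nearest-neighbor similarity, fragment similarity, internal diversity),
    and a seeded synthetic corpus generator for self-contained experiments.
    Chemistry (descriptors, sanitization, fingerprints, BRICS fragments) is
    delegated to RDKit through the system Python.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH
Config/testthat/edition: 3
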