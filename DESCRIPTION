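Package: awespec
Title: Environment-Aware Prediction of X-ray Absorption and Emission Spectra
    from Molecular Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Structure-to-spectrum surrogate modelling for X-ray absorption
    near-edge (XANES) and valence-to-core emission (VtC-XES) spectra of
    coordination complexes. Spectra are encoded in a multiscale Gaussian
    basis with a ridge-regularized projection operator; molecular geometry
    is encoded with weighted atom-centered symmetry functions (wACSF) or a
    pluggable external descriptor provider; an absorber-with-environment
    (AWE) network aggregates neighbour descriptors over learnable soft
    radial shells, fuses them with the absorber descriptor, and predicts
    basis coefficients through residual MLP refinement and per-width-group
    heads. Training minimizes a one-dimensional multiscale structural
    similarity (MS-SSIM) loss plus a coefficient mean-squared error, with
    exact hand-derived gradients and Adam optimization. Bootstrap ensembles
    provide per-spectrum uncertainty estimates. A synthetic coordination
    complex generator with closed-form ground-truth spectra makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'basis.R'
    'wacsf.R'
    'ssim.R'
    'model.R'
    'backprop.R'
    'train.R'
    'uq.R'
    'synthetic.R'
    'checkpoint.R'
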