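Package: methyldyn
Title: Fast Side-Chain Dynamics of Membrane Proteins from Methyl NMR Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of fast (ps-ns) side-chain dynamics of membrane proteins
    from NMR relaxation observables. Implements the Lipari-Szabo model-free
    spectral density and 15N rate forward model, global tumbling-time
    estimation from R2/R1 ratios, the R1*R2 exchange screen, extraction of
    intra-methyl 1H-1H cross-correlated relaxation rates (eta) from intensity
    build-up curves and their conversion to methyl symmetry-axis order
    parameters (O2_axis), decomposition of order-parameter distributions into
    motional classes (including the highly dynamic J-prime class) by mixture
    model selection and k-means, a diffusion-in-a-cone conformational-entropy
    layer, order parameters from bond-vector trajectories, structural-context
    statistics (distance-to-lipid correlation, spatial clustering permutation
    tests), and a synthetic-data generator with known ground truth for
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    mclust,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
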