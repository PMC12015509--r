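Package: cryosiren
Title: Real-Space Heterogeneous Cryo-EM Reconstruction with Sinusoidal
    Hypernetworks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heterogeneous single-particle cryo-EM reconstruction in real
    space. Particle images are encoded into a conformational latent space
    that is explicitly disentangled from pose and contrast transfer
    function (CTF) effects, and any latent point is decoded into a full 3D
    density map by a hypernetwork-conditioned sinusoidal (SIREN) decoder.
    Training couples a physics-based image-formation model (rotation,
    projection, in-plane shift, CTF) with real-space regularizers (L1
    density, negative-value penalty, total variation), a multiresolution
    data objective, and optional focused reconstruction inside a binary
    mask. Includes MRC2014 and RELION STAR input/output, a ground-truthed
    synthetic dataset generator, and latent-landscape analysis (PCA,
    K-means centroid decoding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
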