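Package: axotomo
Title: Simulated X-Ray Microtomography of Axonal Tracts in Freeze-Dried Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulation and analysis pipeline for synchrotron X-ray
    microtomography of freeze-dried brain tissue.  Implements a tissue
    attenuation composition model (water removal, phospholipid and
    phosphorus contributions), seeded synthetic phantoms of striatum-like
    tissue with ground-truth axonal tract centerlines, a parallel-beam
    forward model with Poisson photon noise and Fresnel free-space
    propagation, convolution-back-projection reconstruction with
    single-distance single-material phase retrieval, attenuation-histogram
    and Fourier-domain resolution analyses, SNR-vs-voxel-width scaling, and
    an automatic axonal tract tracer whose skeletonized wire models
    round-trip through a Protein Data Bank format dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
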