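Package: polychamber
Title: Individual-Based Chamber Model and Single-Cell Statistics for
    Bacterial Growth on Polysaccharides
Version: 0.1.0
Authors@R:
    person("Polychamber", "Developers", email = "maintainer@polychamber.org",
           role = c("aut", "cre"))
Description: Simulates bacterial growth on a diffusible polysaccharide inside a
    flow-flushed quasi-2D microfluidic chamber with an individual-based
    reaction-diffusion model (polymer, secreted depolymerase, oligomer fields;
    Monod uptake and growth; Dirichlet boundary representing flushing flow),
    and provides the accompanying single-cell and batch statistical analyses:
    birth-time binning, density-dependent growth-rate regression with half-max
    cell number, logistic chamber-count fits, founder-lineage aggregation
    metrics, exact Mann-Whitney tests with Hodges-Lehmann differences,
    plate-reader growth-curve metrics, and secretion-halo correlations. A
    synthetic-data generator with recorded ground truth replaces microscopy
    and plate-reader inputs so that every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
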