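Package: dbsfield
Title: Electric Field and Axon Activation Modelling for Deep Brain
    Stimulation Leads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quasi-static volume-conductor modelling of deep brain
    stimulation (DBS). Builds parametric models of four DBS lead designs
    (Medtronic 3389, St. Jude 6148 and 6180, SureStim1) with symmetric and
    field-steering contact configurations, embeds them in homogeneous or
    heterogeneous voxel-based conductivity volumes (from T2-weighted MR
    intensity classification or a seeded synthetic brain generator), and
    solves the steady-current equation with a conservative finite-volume
    scheme on a locally refined grid, in voltage or current mode with
    floating inactive contacts and a 0.25 mm peri-electrode space. A
    myelinated-axon cable model driven by the extracellular potential
    computes activation distances over amplitude and fibre-diameter
    sweeps and calibrates the 0.2 V/mm electric-field isolevel. Field
    comparison metrics include isosurface volume, maximal isocontour
    extension per plane, and steering asymmetry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
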