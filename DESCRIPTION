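Package: mitovoxel
Title: Voxel-Scale Mitochondrial Phenotyping of Brain Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for plate-based mitochondrial
    phenotyping of physically voxelized brain tissue. Generates synthetic
    96-well assay campaigns over a voxelized tissue slab (kinetic colorimetric
    traces, frozen-tissue respirometry phases, duplex qPCR triplicates, MRI
    metrics, and single-nucleus expression), derives batch-corrected enzymatic
    and mtDNA features, computes the volumetric density and respiratory
    capacity metrics MitoD, TRC and MRC, places features into NIfTI volumes in
    a stereotaxic space, embeds voxel profiles with UMAP, fits stepwise
    backward regressions of mitochondrial features on neuroimaging metrics,
    and scores pseudobulk mitochondrial pathway expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    mclust,
    uwot,
    e1071
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
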