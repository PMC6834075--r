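Package: phaseCT
Title: Propagation-Based Phase-Contrast X-Ray Imaging and Tomography of
    Protein Crystals in Opaque Mounts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for planning, simulating and processing in-line
    (propagation-based) phase-contrast X-ray imaging and tomography
    experiments on macromolecular crystallography beamlines, aimed at
    localizing protein crystals inside optically opaque mounts such as
    cryocooled lipidic cubic phase. Provides closed-form beamline
    coherence and compound-refractive-lens optics calculators, a
    thin-sample absorbed-dose model, voxel phantom generators, a
    partial-coherence Fresnel hologram simulator, an effective-source-size
    fitter for fiber interference patterns, and the full processing chain:
    SSIM-matched flat-field correction, Paganin single-distance phase
    retrieval, wavelet-Fourier destriping, parallel-beam filtered
    backprojection with the Shepp-Logan filter, automatic segmentation and
    Wavefront OBJ mesh export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, Preprocessing
Collate: 
    'phaseCT-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'materials.R'
    'utils.R'
    'pipeline.R'
    'recon.R'
    'segment.R'
    'mesh.R'
    'optics.R'
    'phantom.R'
    'holosim.R'
    'sourcefit.R'
    'dose.R'
    'io.R'
    'cli.R'
    'destripe.R'
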