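Package: polOrder
Title: Orientational Order Mapping from Excitation-Resolved Fluorescence
    Polarization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the in-plane orientational order of fluorophore
    dipole ensembles from four-polarization excitation-resolved
    fluorescence microscopy stacks. Provides flat-field correction and
    pixel-wise normalization, per-pixel Order Factor and azimuth maps,
    top-hat/Otsu segmentation of punctate junctions with local
    signal-to-background filtering, object-level order and axial circular
    disorder statistics, border line scans, group-comparison statistics
    (Kruskal-Wallis with Dunn's post hoc, one-way ANOVA with Sidak
    pairwise tests, paired t-tests over a neighbor-and-control comparison
    scheme), and a forward simulator of polarized-excitation imaging of
    dipole ensembles with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    tools,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
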