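Package: ssbdyn
Title: Single-Molecule Analysis of SSB-ssDNA Binding Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of single-stranded DNA-binding protein
    (SSB) dynamics on ssDNA from single-molecule and bulk assays: extensible
    freely-jointed-chain (eFJC) fitting of force-distance curves with
    between-curve energy integration, salt-induced ssDNA compaction decay
    kinetics from TIRF length traces, a two-state wrapped-to-bound-to-free
    dissociation model with photobleaching correction, footprint-based
    template coverage arithmetic, two-color binding-competition
    quantification, 1:1 Langmuir fits of biolayer-interferometry
    sensorgrams, and Gaussian fits of mass-photometry event distributions.
    Synthetic-data generators with fixed seeds emulate every assay so the
    full pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    mclust,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
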