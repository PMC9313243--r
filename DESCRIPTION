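Package: qdcoloc
Title: Quantum-Dot Boundary Colocalization and Plant Growth Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the colocalization of quantum-dot-labelled small
    molecules (such as quantum-dot-melatonin conjugates) with plant cell
    boundaries in fluorescence micrographs. Provides a synthetic-scene
    generator with known ground truth (anisotropic cell tessellations,
    Gaussian-PSF emitters, Poisson/Gaussian camera noise), per-pixel
    cell-boundary probability maps (a trainable pixel classifier and a
    deterministic multiscale ridge filter), Laplacian-of-Gaussian spot
    detection with sub-pixel centroid refinement, the boundary-colocalized
    fraction statistic at a probability threshold with permutation-based
    group comparison, Mendelian segregation chi-square tests, and a
    growth/gravitropism statistical battery (plate averaging of
    pseudoreplicates, one-way ANOVA with Holm-Sidak comparisons, two-way
    ANOVA with Sidak comparisons, and linear-trend dose contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    tiff,
    jsonlite,
    yaml,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
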