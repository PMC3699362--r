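Package: calomorph
Title: Wing-Shape Allometry in Calopterygid Damselflies via Area Moments
    and Geometric Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the allometry of damselfly wing shape.
    Computes the non-dimensional radius of the second moment of wing area
    (RSM) from wing outlines by strip integration, quantifies wing shape by
    geometric morphometrics (Generalized Procrustes Analysis with sliding
    semilandmarks, partial warps and the uniform component, thin-plate
    spline deformation grids, allometric shape scores), and relates shape
    to size and wing-coloration group both conventionally (polynomial
    regression, MANCOVA, ANCOVA, general linear models) and
    phylogenetically (Felsenstein independent contrasts with branch-length
    transformation, Brownian-motion simulation-null phylogenetic ANOVA).
    Includes a synthetic-data generator that emulates the statistical
    structure of a museum-specimen wing survey so every pipeline stage is
    testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
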