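Package: vitmech
Title: Vitelline Membrane Mechanics from Drop Shape, Tensile Traces and
    Embryo Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the mechanics of the avian vitelline
    membrane (VM) and its effect on early embryo morphogenesis. Implements
    an axisymmetric tensed-membrane sessile-drop model (Young-Laplace
    shooting solver with contact angle pi) that maps yolk puddle geometry
    to membrane tension and inverts observed yolk indices to tension
    estimates; analysis of scale weight-reading traces for native and
    maximum VM tension; extraction of stiffness (rate of force increase)
    from force-probe indentation traces; embryo morphometrics (elongation,
    convergence and segmentation speeds, posterior neural tube width,
    glycoprotein fibre density by Otsu binarization); synthetic-data
    generators with known ground truth for every input type; and group
    statistics reporting (Welch/pooled t-tests, one-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
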