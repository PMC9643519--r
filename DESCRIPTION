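Package: ontether
Title: Finite-Element Simulation of Optic Nerve Tethering During Ocular
    Adduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Parametric finite-element pipeline for the biomechanics of
    optic nerve (ON) tethering during ocular adduction. Provides regional
    reduced-polynomial (Yeoh-family) hyperelastic tissue cards, a
    parametric globe/nerve geometry in the 26-degree adducted
    straightened-nerve configuration, quadratic-element meshes (6-node
    plane-strain triangles and 10-node tetrahedra), a total-Lagrangian
    Newton solver with follower pressure loads for intraocular and
    intracranial pressure, and a sensitivity case matrix over
    stiff/compliant tissue-property combinations with region summaries
    (von Mises stress in kPa, maximum principal logarithmic strain in
    percent) and lamina cribrosa edge displacement in micrometres.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
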