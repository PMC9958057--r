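Package: rrtopo
Title: Reduced Reverse Degree Topological Indices and Curvilinear QSPR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes reduced-reverse-degree and classical degree-based
    topological indices of molecular graphs, derives closed-form linear
    index polynomials for repeat-unit (polymeric) graph families from
    symbolic edge partitions, and provides a curvilinear (linear and
    quadratic) QSPR toolkit with chi-square goodness-of-fit, RMSE and
    residual diagnostics. Ships the benzenoid hydrocarbon property table,
    the printed Randic-type index column, the fitted model coefficients
    and the hyaluronic-acid-paclitaxel conjugate edge partition as
    plain-text fixtures, together with a hexagonal-lattice benzenoid
    graph builder and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
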