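Package: evograph
Title: Exact Birth-Death Fixation Probabilities and Structural Metrics for
    Small Weighted Digraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact computation of Moran birth-death fixation probabilities on
    small weighted directed graphs by assembling and solving the full
    2^N-state master equations, with a lumped fast path for circular-flow
    graphs and a closed form for complete bipartite graphs.  Constructs
    biased cycles, dual circular flows, partial bipartite and single-link
    graphs as validated row-stochastic weighted digraphs, and computes their
    structural metrics: stationary distributions, the similarity-transformed
    graph Laplacian and its antisymmetric part, closed-form characteristic
    polynomials, subset and graph conductance (Cheeger constant), Estrada
    communicability, and Kemeny-Snell expected hitting times.  Includes an
    exact rational arithmetic backend, a temperature-profile tuning solver
    for generalized circular flows, bisection crossing finders, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
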