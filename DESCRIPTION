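Package: deltadiscrim
Title: Symmetric Model Discrimination Designs via Flexible Nominal Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of exact experimental designs for
    symmetric discrimination between two rival nonlinear regression models.
    Implements the delta criterion, a linearized distance between the
    mean-value surfaces of the two models over cuboid "flexible nominal sets"
    dilated by a tuning parameter r, evaluated by box-constrained least
    squares.  Provides a KL-type exchange heuristic and complete enumeration
    for maximizing the criterion over n-point designs on a finite design
    space, iterative and linear-programming computations of set upper bounds
    on the dilation parameter, and Monte-Carlo evaluation of likelihood-ratio
    discrimination hit rates under normal and mean-matched log-normal error
    models, including the built-in enzyme-kinetics example of competitive
    versus noncompetitive inhibition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
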