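Package: ratingwalk
Title: Markov and Quantum Random-Walk Models of Sequential Rating Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares two random-walk accounts of how people produce
    successive judgements on a bounded rating scale: a classical birth-death
    Markov process and a quantum walk driven by a tridiagonal (crystal)
    Hamiltonian, both defined on a fine lattice of evaluation states mapped
    onto the observable rating categories.  The models predict the full joint
    distribution of two ratings made in either question order, including the
    order effects that arise when the two questions are incompatible.  The
    package provides the lattice and projector machinery, matrix-exponential
    propagators, a non-judgemental mixture component, sum-of-squared-error and
    multinomial likelihood (G-squared) estimation with multi-start
    derivative-free optimisation, a saturated-versus-restricted G-squared test
    for question-order effects, and a trial-level synthetic experiment
    generator.  Ships the observed joint rating tables from a study of
    public-service-announcement effectiveness judged from one's own versus a
    friend's perspective.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lhs,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
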