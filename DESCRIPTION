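Package: colchain
Title: Iterated Learning of Colour-Term Systems over the World Color
    Survey Array
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the cultural transmission of colour naming systems
    by iterated learning over the 330-chip World Color Survey stimulus
    array, and analyses convergence of transmission chains towards a
    reference naming corpus using the variation-of-information partition
    metric. Provides generators for hue, lightness and random initial
    partitions, an exemplar-based learner with a tunable perceptual bias,
    a synthetic multi-language naming-corpus generator, the rotation null
    control along the circular hue dimension, and the supporting
    evolutionary-dynamics theory: the neutral replicator equation, exact
    mutation matrices for Bayesian posterior-sampling learners on
    enumerable hypothesis spaces, and the equivalence of the replicator
    equilibrium, the Markov-chain stationary distribution, and the
    learner's prior.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
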