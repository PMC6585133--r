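Package: padeq
Title: Model Adequacy Testing for DNA Substitution Models by Binned
    Goodness-of-Fit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Absolute goodness-of-fit (adequacy) testing for DNA
    substitution models in phylogenetics. Site patterns of an alignment
    are summarised by their nucleotide frequency vectors and grouped
    into bins, either exactly (equal-frequency binning for four taxa) or
    by K-means clustering of the frequency vectors; observed bin counts
    are compared with expected counts under the fitted null model
    (computed exactly or by parametric-bootstrap simulation) with a
    Pearson chi-square statistic on K-1 degrees of freedom. Includes
    maximum-likelihood model fitting and tree search (via 'phangorn'),
    an alignment simulator for parametric bootstrapping, the
    likelihood-ratio and Goldman-Cox comparator tests, guidance for the
    number of simulated sites, and a harness for size/power simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
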