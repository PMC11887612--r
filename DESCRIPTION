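Package: pomediate
Title: Bayesian Potential-Outcomes Mediation Analysis of Maternal Health Disparities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how prepartum body mass index (BMI) and gestational
    weight gain (GWG) mediate Black/non-Black disparities in maternal birth
    outcomes using Bayesian estimation of potential outcomes. Outcome counts
    in the eight cells defined by race and the two binary mediators are
    modelled as independent binomials with Uniform(0,1) priors, giving exact
    Beta conjugate posteriors for every cell and for marginals with one or
    both mediator indices collapsed. From these the package computes posterior
    distributions of the total effect, controlled direct effects with
    mediators fixed at their optimal level, and the percent of the disparity
    attributable to each mediator. Includes record-level preparation of
    natality-style birth data (BMI derivation, 40-week GWG correction,
    missingness filtering, aggregation) and a calibrated synthetic-data
    generator so the entire pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
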