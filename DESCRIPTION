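Package: allelic
Title: Allelic-Manifold Analysis of Cis-Regulatory Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Thermodynamic (statistical-mechanics) models of bacterial
    transcription under simple repression and activation, and inference of
    in vivo Gibbs free energies of TF-DNA, TF-RNAP and RNAP-DNA
    interactions from paired reporter measurements. Paired transcription
    rates measured with and without an active transcription factor, across
    an allelic series of RNAP binding sites, trace a one-dimensional
    "allelic manifold" whose geometry encodes binding factors and
    cooperativities. The package provides the closed-form manifold models,
    regime classification, nonlinear least-squares fitting with
    per-promoter nuisance parameters, bootstrap confidence intervals,
    outlier and collapse diagnostics, titration (power-law) analysis, and
    a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
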