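Package: mutasynth
Title: In Silico Product Enumeration and Exact-Mass Annotation for
    Siderophore Mutasynthesis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for precursor-directed biosynthesis (mutasynthesis) of
    catechol siderophores in engineered bacterial hosts. Enumerates candidate
    nonribosomal-peptide products from a registry of amine precursors and the
    2,3-dihydroxybenzoate (DHB) pathway rules, computes monoisotopic masses and
    protonated m/z values, predicts rule-based MS/MS fragments, annotates
    observed accurate-mass peak lists with ppm tolerance, summarizes precursor
    incorporation, and estimates maximal specific growth rates from OD curves.
    Includes seeded simulators for spectra and growth curves so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
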