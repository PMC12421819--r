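Package: c1flux
Title: Stoichiometric and Isotope-Tracer Modelling of Synthetic C1
    Assimilation via the Reductive Glycine Pathway
Version: 0.1.0
Authors@R:
    person("c1flux", "maintainers", email = "c1flux@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing engineered formatotrophic and
    methylotrophic growth in Pseudomonas putida through the reductive
    glycine pathway (rGlyP). Builds a curated core stoichiometric model of
    central carbon metabolism extended with the rGlyP modules and C1
    oxidation reactions, solves flux balance problems (growth maximisation,
    theoretical yields, parsimonious flux maps normalised to substrate
    uptake), propagates 13C labels through curated carbon atom maps to
    predict positional isotopomer and mass-isotopomer distributions of
    reporter amino acids, discriminates TCA-route hypotheses against
    measured labelling patterns, corrects raw GC-MS fragment
    mass-isotopomer distributions for natural isotope abundance, estimates
    growth and uptake kinetics from time series, and generates synthetic
    datasets with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
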