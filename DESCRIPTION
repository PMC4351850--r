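Package: sitabm
Title: Agent-Based Simulation of Transgenic Sterile Insect Technique
    Campaigns in Anopheles gambiae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An hourly-resolution, individual-based model of an Anopheles
    gambiae population under four transgenic sterile insect technique (SIT)
    implementations: early- or late-acting, bisex or female-killing dominant
    cell-lethal transgenes. Simulates the full mosquito lifecycle (egg,
    larva, pupa, immature adult, and the adult gonotrophic cycle) with
    density-dependent larval mortality in a single larval habitat,
    single-locus dominant lethal genetics, heritable mating competitiveness,
    weighted mate choice, daily fixed-number male release campaigns, and the
    ten daily population measures used to compare implementations, including
    fecundity potential and control-normalized suppression factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
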