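Package: qtlcoloc
Title: Co-Localization Analysis of Colon and Lung Cancer Susceptibility QTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether quantitative trait loci (QTLs) for
    different cancers cluster in the genome, built around a mouse
    recombinant-congenic cross design.  Provides genetic-map interval
    arithmetic over centimorgan region tables; a simulator for F2
    intercrosses of recombinant congenic strains with overdispersed tumor
    count, size and load phenotypes; a marker-based ANOVA QTL scan with
    pairwise epistasis search, backward elimination and Lander-Kruglyak
    genome-wide correction; a Poisson-model concordance test for the
    presence patterns of two locus types across jointly tested "overlap"
    regions; and a binomial proximity test for clustering of orthologous
    loci near anchor loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
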