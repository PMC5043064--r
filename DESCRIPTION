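Package: msatpop
Title: Microsatellite Population Genetics: Diversity, Exact HWE, Null
    Alleles, F-Statistics and Population Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for codominant diploid microsatellite
    genotypes sampled from many populations: per-population diversity
    statistics (allele counts, rarefied allelic richness, effective
    alleles, observed and expected heterozygosity, inbreeding
    coefficients and the derived outcrossing rate), exact
    Hardy-Weinberg tests by complete enumeration or a Guo-Thompson
    Markov chain, sequential Bonferroni correction, expectation
    maximisation estimation of null-allele frequencies with an
    ENA-corrected Weir-Cockerham theta and an FIS-versus-null-frequency
    diagnostic, allele-size permutation tests contrasting RST with its
    permutational null, Nei genetic distances with neighbor-joining
    population trees and locus bootstrap, and a forward-time
    Wright-Fisher simulator (island-model migration, partial selfing,
    stepwise mutation, founder bottlenecks, null-allele artifacts) that
    provides ground truth for validating every estimator. Reads and
    writes GENEPOP files and a long-format CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
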