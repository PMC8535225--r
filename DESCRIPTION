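Package: captivekin
Title: Marker-Based Genetic Assessment and Studbook Reconciliation for
    Captive Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular genetic assessment of small managed
    (captive) populations and for reconciling studbook pedigrees with
    marker data.  Implements sequence diversity statistics and neutrality
    tests (Tajima's D, Fu and Li's D*) for mitochondrial and MHC
    haplotypes, haplotype-pair phasing against a known panel, minimum
    spanning networks, microsatellite diversity statistics (observed and
    unbiased expected heterozygosity, F_IS, rarefied allelic richness,
    probabilities of identity), Monte-Carlo Hardy-Weinberg and linkage
    disequilibrium tests, maximum-likelihood pairwise relatedness with
    IBD-coefficient estimation and simulation-based confidence sets,
    likelihood-based parentage assignment (LOD and Delta scores) with
    MHC-haplotype trio checks, the linkage-disequilibrium single-sample
    effective population size estimator with jackknife confidence
    intervals, pedigree kinship and dyad classification, a
    genetics-versus-studbook consistency engine, and a synthetic-data
    generator (pedigree simulation, gene dropping, error injection,
    Wright-Fisher and neutral coalescent simulation) for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
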