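Package: liabmr
Title: Liability-Threshold Simulation, Trio Association, Polygenic Scores
    and Bidirectional Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying quantitative subphenotypes of dichotomous
    traits under the liability-threshold model. Provides a generative
    simulator for block-LD genotypes, trios ascertained for an affected
    child, and quantitative phenotypes linked to genetic liability through
    causal, confounded or reverse-causal paths; single-SNP association
    engines (transmission disequilibrium test on trios and duos, allelic
    case-control, covariate-adjusted linear GWAS); fixed-effect
    inverse-variance meta-analysis of summary statistics; LD clumping;
    polygenic risk scores with polygenic-TDT p-value threshold selection
    and a minimum-detectable genetic-correlation power calculation; a
    two-sample Mendelian randomization suite (inverse-variance weighted,
    MR-Egger, weighted median, weighted mode, leave-one-out, Steiger
    directionality) on harmonized summary statistics; and a decision
    framework that classifies bidirectional MR evidence into
    liability-subphenotype, confounded or bidirectional scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
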