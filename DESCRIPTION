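Package: allodose
Title: Expression Inheritance, Homoeolog Regulation and Genomic Dose
    Gradients in Hybrids and Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gene-expression inheritance and
    dose-adjusted allele-specific (homoeolog) regulation in diploid and
    triploid interspecific hybrids. Provides a negative-binomial
    synthetic-data generator with an explicit cis/trans regulatory
    architecture and a tunable trans cross-talk parameter, in-silico
    additive hybrids built by count-level read mixing, species-diagnostic
    SNP selection from VCF calls, median-of-ratios normalization and NB GLM
    contrasts with type-II ANOVA, classification of genes into the twelve
    expression-inheritance categories, cis/trans regulatory divergence
    calls from dose-adjusted allelic ratios, homoeolog up/down modulation
    statistics (skewness, MAD, Fligner-Killeen, permutation tests), and
    multivariate ordination with broken-stick axis selection, PERMANOVA,
    jackknifed canonical variate analysis and genomic-dose gradient
    fitting with biplot rotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    vegan,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
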