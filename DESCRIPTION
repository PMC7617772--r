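Package: invrad
Title: Detection and Population-Genetic Analysis of Large Polymorphic
    Chromosomal Inversions from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and analysing large polymorphic
    chromosomal inversions in species radiations from multi-sample SNP
    callsets. Implements windowed principal-coordinate profiling of
    pairwise genetic distances with k-means outlier-region detection,
    multi-step PCA genotyping of inversion karyotypes with outgroup
    polarisation, rephasing of heterozygous SNPs by inversion genotype,
    inversion-correlated SNP scans with McDonald-Kreitman, neutrality
    index, direction-of-selection and correlation-binned dN/dS
    statistics, Patterson's D (ABBA-BABA) with block jackknife and an
    inversion-state-conditioned introgression experiment, pairwise
    divergence-time estimation, exact Hardy-Weinberg heterozygote-excess
    and sex-association tests, and seeded simulators (structured
    coalescent radiation with planted inversions, an interspecific
    pedigree cross, and a two-background Wright-Fisher forward model of
    selection on inversion haplotypes) that provide planted truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    seqinr,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
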