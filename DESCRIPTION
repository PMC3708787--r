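Package: sweepscan
Title: Selection Scans on Phased Haplotype Panels: F_ST Outliers, Haplotype
    Blocks and Long-Range Haplotype Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting natural selection in multi-population phased
    haplotype panels. Implements Weir-Cockerham pairwise F_ST on chromosome
    counts with chromosome-wide empirical percentile ranking, an island-model
    coalescent F_ST-outlier (FDIST-style) neutrality test with migration-rate
    calibration and conditional outlier probabilities, Gabriel-rule haplotype
    block construction from D-prime confidence intervals, and extended
    haplotype homozygosity (EHH) with relative EHH (REHH) scored against
    frequency-binned empirical null distributions. Includes readers and
    writers for phased VCF, IMPUTE-style and tabular haplotype formats and
    genetic maps, plus synthetic-data generators (Balding-Nichols island
    panels and a forward Wright-Fisher simulator with recombination and
    planted selective sweeps) so the whole pipeline can be exercised and
    validated on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
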