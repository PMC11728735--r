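Package: edscan
Title: Bulked-Segregant QTL Scanning with the Euclidean-Distance Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for bulked-segregant analysis (BSA-seq) of quantitative
    traits from pooled sequencing of phenotypically extreme bulks. Computes
    the per-SNP Euclidean distance (ED) between the allele-frequency vectors
    of a high-trait and a low-trait pool, applies the ED^x power transform,
    smooths the profile along each chromosome with a tricube distance kernel,
    derives per-chromosome significance thresholds (median plus three
    standard deviations), calls above-threshold candidate regions, intersects
    candidate regions across replicate years, and annotates them with gene
    models from GFF3. A forward simulator of pooled-sequencing experiments
    with known quantitative trait loci provides ground truth for validating
    every stage. Includes variant quality-control filters (depth validity,
    missingness, minor allele frequency, biallelic-SNP restriction) and
    phenotype distribution summaries used to assess suitability for bulk
    segregant analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    e1071,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
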