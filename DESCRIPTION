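Package: sweepscan
Title: Selection-Signature Scans from Two-Population SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for detecting selective sweeps between
    two diverged populations from diploid SNP genotypes. Reads multi-sample
    VCFs into a dosage matrix, applies GATK-style hard filters and minor-allele
    frequency / missingness QC, computes per-population diversity statistics
    (polymorphism information content, observed heterozygosity, expected
    heterozygosity, nucleotide diversity, per-individual variant counts),
    linkage-disequilibrium decay curves, genotype PCA and neighbor-joining
    trees, a sliding-window Weir-Cockerham Fst and nucleotide-diversity-ratio
    scan with joint-tail candidate-region selection and gene-interval
    annotation, and Fisher exact-test validation of candidate SNPs against
    trait groups. Ships a two-population Wright-Fisher simulator (site-wise
    and haplotype modes, with localized sweeps, missingness and
    trait-associated loci) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
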