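Package: popgenscan
Title: Window-Based Population-Genomic Scans for Diversity,
    Differentiation and Inbreeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Population-genomic analysis of biallelic SNP genotype
    matrices: VCF input with site filtering (genotype depth, site quality,
    call rate, monomorphic removal), pooled-heterozygosity selection scans
    (Hp and ZHp) in overlapping sliding windows, per-SNP Weir-Cockerham
    Fst with windowed mean Fst, runs-of-homozygosity detection and Froh
    genomic inbreeding coefficients under a stringency grid, a screen for
    perfectly sex-discordant markers, genotype PCA for population
    structure, sequencing QC summaries, and a two-population
    Balding-Nichols genotype simulator with planted homozygous tracts and
    a planted sex-linked locus for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
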