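Package: erhaplo
Title: Haplotype-Class Selection Analysis for Evolve-and-Resequence
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring selection on haplotype classes in
    Evolve-and-Resequence (E&R) experiments with pooled sequencing
    (Pool-seq). Reads PoPoolation2 sync allele-count files and founder
    haplotype VCFs; calls haplotype classes from founder haplotypes,
    discovers diagnostic marker SNPs and computes nucleotide diversity;
    converts marker-SNP frequencies into haplotype-class frequency
    trajectories; estimates temporal effective population size from
    allele-frequency change; fits co-dominant Wright-Fisher selection
    coefficients and class contrasts; runs classic and drift-adjusted
    Cochran-Mantel-Haenszel scans; fits probit dose-response curves
    (LD50) to insecticide bioassays; and generates complete synthetic
    experiments with known truth for validation.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    cluster,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
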