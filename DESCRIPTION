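Package: polyBSA
Title: RNA-Seq Bulked Segregant Analysis for Allopolyploid Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bulked segregant analysis (BSA) of RNA-seq allele counts in
    allopolyploids, where reads from homoeologous subgenomes dilute and
    confound the allele-frequency signal of a selected locus. Simulates the
    full experiment (selfing pedigrees with heterozygote selection, bulk
    formation, depth sampling with homoeologous contamination), classifies
    SNP sites into subgenome-specific allelic variants versus homoeologous
    polymorphisms using parental-pairwise and tetraploid-reference evidence,
    computes polarized SNP-index and averaged delta-SNP-index tracks,
    localizes the target locus with the Steel-Dwass all-pairs rank test,
    designs dCAPS/CAPS genotyping assays validated by in-silico restriction
    digestion, and closes the loop with two-point linkage estimation on a
    simulated mapping population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
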