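Package: plastotyper
Title: Organelle Plasmotyping from Mixed Chloroplast-Mitochondrial NGS Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for plasmotyping plant samples from
    next-generation sequencing of co-purified chloroplast and mitochondrial
    DNA. Simulates mixed-organelle paired-end reads with planted haplotypes,
    quality-trims and assigns reads to a double (chloroplast + mitochondrial)
    reference, calls haploid consensus variants, annotates them against gene
    models (codon position, amino-acid change, HGVS p. strings), screens
    plastid C-to-U RNA-editing candidates, classifies chloroplast and
    mitochondrial DNA types into plasmotypes, builds outgroup-rooted maximum
    parsimony cladograms with parallel/reverse homoplasy classification, and
    reconciles sequence-level types with variant-aware in silico restriction
    (RFLP) patterns on circular replicons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    ape,
    phangorn,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    vcfR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
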