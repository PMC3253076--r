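Package: haplodiv
Title: Nucleotide Diversity and Lineage-Specific Substitutions from
    Haplotype-Resolved BAC Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls SNPs and indels between quality- and complexity-masked
    pairwise alignments of alternative haplotype assemblies, computes
    per-locus and pooled nucleotide diversity (pi) and indel length
    spectra, estimates duplication divergence with the Kimura
    two-parameter distance and its standard error, classifies coding
    SNPs as synonymous or nonsynonymous with Nei-Gojobori (1986) site
    counting, and infers radical versus conservative lineage-specific
    amino-acid replacements on a fixed rodent phylogeny by strict
    parsimony.  Includes a seeded synthetic-data generator producing
    haplotype pairs, phred quality tracks, CDS annotations and
    multi-species protein alignments with known ground truth, so the
    whole pipeline is testable without external sequence archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
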