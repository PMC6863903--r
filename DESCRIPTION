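Package: strainpop
Title: Strain-Resolved Population Genetics of Symbiont Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream population-genetic analysis of strain-deconvolved
    shotgun metagenomes, developed around chemosynthetic endosymbionts of
    deep-sea mussels. From per-sample nucleotide count tables over a core
    genome and a set of reconstructed strain haplotypes, the package computes
    intra- and inter-sample nucleotide diversity, the fixation index, pN/pS
    and a two-level Neutrality Index, unfolded allele frequency spectra,
    strain presence/dominance calls, phylogenetic species evenness and
    weighted UniFrac. It also provides the co-abundance (canopy) binning that
    defines metagenomic species and their core genomes, a filtered
    single-linkage gene-catalog clustering step, and a synthetic community
    simulator that generates clade-structured strain genomes, Dirichlet
    strain mixtures and pileup-like allele counts so every stage can be
    exercised without raw sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    vegan
Suggests:
    mclust,
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
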