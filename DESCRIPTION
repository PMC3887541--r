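Package: trscape
Title: Tandem Repeat Landscapes in Genomes and Gene Regions
Version: 0.1.0
Authors@R: person("R.", "Lander", email = "rlander@example.org",
    role = c("aut", "cre"))
Description: Detects perfect and imperfect tandem repeats (unit sizes 1-50 bp)
    in genome assemblies, canonicalizes repeat motifs, materializes intragenic
    (5'-UTR, CDS, intron, 3'-UTR) and flanking intergenic windows (UI200/UI500/
    UI1000 and DI200/DI500/DI1000) from GFF3 gene annotations, and computes the
    comparative statistics used in genome-wide tandem-repeat surveys: densities
    in bp/Mbp, genome-normalized relative densities, motif and unit-size
    frequency tables, decile positional profiles, per-mRNA repeat presence
    frequencies, and Pearson/ANOVA/Tukey comparisons across regions. A
    synthetic-genome generator plants repeat arrays with known coordinates,
    motifs and mutations so every pipeline stage can be validated against
    ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
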