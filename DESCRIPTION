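Package: retropop
Title: Population Analysis of Centromere-Specific LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to annotate and analyse populations of centromere-specific
    LTR retrotransposons (such as the wheat RLG_Cereba and RLG_Quinta families)
    on genome assemblies. Implements paired-LTR discovery of full-length copies
    with family size windows, internal coding-sequence validation and
    target-site-duplication filtering; insertion dating from 5'/3' LTR
    divergence under the Kimura two-parameter model; copy-to-consensus variant
    calling into VCF with principal component analysis and pairwise SNP
    distances; CENH3 ChIP-seq hot-spot detection with TE-family classification
    and projection of per-base coverage onto family consensus coordinates; and
    a centromere-midpoint Mantel test relating genetic to positional distance.
    A synthetic-genome simulator with known ground truth (implanted elements,
    subfamily haplotypes, target-site duplications, decoys and ChIP coverage
    tracks) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
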