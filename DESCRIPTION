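Package: fsalign
Title: Frameshift-Aware Pairwise Alignment of Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Global pairwise alignment of protein-coding DNA sequences
    (CDS) under a scoring model that penalizes both the initiation and
    the length of frameshifted translation. Aligned codons are
    partitioned into in-frame matches, frameshift extensions, codon
    indels and frameshift initiations; the score combines amino-acid
    substitution scores (halved across frameshifted codons), nucleotide
    scores for matched frameshift-initiation nucleotides, and separate
    opening/extension penalties for frameshifts and codon gaps. Provides
    the O(nm) dynamic-programming aligner with traceback (linear or
    affine codon-gap penalties), an exhaustive enumeration oracle for
    small inputs, six alignment-composition criteria, deterministic
    synthetic fixtures, FASTA input/output and an all-pairs driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Biostrings, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
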