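Package: mhcselect
Title: Selection and Diversity Analysis of MHC Amplicon Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-level molecular-evolution toolkit for multigene-family
    (MHC) allele alignments: reading-frame aware codon alignments and
    translation, nucleotide diversity and segregating-site statistics,
    pairwise dN/dS by Nei-Gojobori (Jukes-Cantor corrected) and
    Pamilo-Bianchi-Li (Kimura 2-parameter) distances restricted to
    peptide-binding-residue site masks, codon-bootstrap Z-tests of positive
    selection, permutation chi-square tests of association between
    positively selected sites and peptide-binding residues, a between-class
    selection comparison statistic, amplicon-genotype quality control
    (read-count filtering, replicate reproducibility, anchor-residue allele
    validation, transcript expression cross-check), and seeded simulators
    for codon alignments under site-specific selection and for multi-locus
    genotype datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
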