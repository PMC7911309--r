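Package: pnatools
Title: Design and Characterization of Anti-miRNA Peptide Nucleic Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the rational design of peptide nucleic acid (PNA)
    oligomers directed against mature microRNAs, and for their physico-
    chemical characterization. Enumerates candidate anti-miR PNAs with
    seed-region coverage, screens them for self-complementarity (parallel
    and antiparallel) and for off-target complementary stretches in
    transcript sets, and generates composition-preserving scrambled
    controls. Models antiparallel nucleic-acid duplexes: gapless pairing
    maps with bond-class counts (A:U, G:C, G:U wobble), percent
    complementarity, and a dynamic program that locates the best binding
    site of a short strand (a miRNA) within a long one (a 3'-UTR).
    Scores binding-site conservation across orthologous aligned UTR
    segments. Computes average and monoisotopic molecular weights of
    peptide-PNA conjugates from elemental residue compositions together
    with electrospray-ionization multiply-protonated charge-state m/z
    series. Includes a deterministic synthetic-fixture generator with
    planted ground truth, FASTA and conjugate-descriptor parsers, and a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
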