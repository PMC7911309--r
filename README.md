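# pnatools

Design and characterization of anti-miRNA peptide nucleic acids (PNAs)
in R.

PNAs are uncharged DNA analogues on an N-(2-aminoethyl)glycine
backbone that bind complementary RNA by Watson–Crick pairing. A PNA
complementary to a mature microRNA (an *anti-miR*), usually carrying
an N-terminal octaarginine (R8) peptide for cell uptake, sequesters
that miRNA and de-represses its targets. `pnatools` covers the desk
work around such molecules, for researchers designing anti-miR
experiments:

- **Design** (`enumerate_candidates`, `validate_design`): every
  18-mer window of a mature miRNA yields a candidate PNA — the
  T-lettered reverse complement of the window — screened for seed
  coverage (miRNA nt 2–8), self-complementarity in antiparallel *and*
  parallel orientation, and off-target complementary runs in a
  transcript set.
- **Scrambled controls** (`make_scrambled_control`): permute exactly
  *n* bases (default 4) of the parent PNA, preserving the base
  multiset — and therefore the conjugate mass — while suppressing
  hybridization to the target (seeded, deterministic).
- **Duplex modeling** (`pair_gapless`, `find_best_site`): gapless
  antiparallel pairing maps with bond-class counts (A:U, G:C,
  G:U wobble) and percent complementarity
  `n_paired / query_len`; plus a semi-global dynamic program
  scoring `+3` per G:C, `+2` per A:U, `+1` per G:U with affine bulge
  penalties, which locates the best binding window of a short strand
  in a long one (miRNA in 3'-UTR).
- **Conservation** (`column_identity`, `site_conservation`):
  per-column identity of orthologous aligned UTR segments to a
  reference row, averaged over binding-site intervals.
- **Mass spectrometry** (`conjugate_mw`, `esi_series`): average and
  monoisotopic MW of peptide–PNA conjugates from elemental residue
  compositions, and the multiply-protonated ESI series
  `m/z = (M + n·1.00728)/n`.
- **Profile utilities** (`classify_fold_changes`, `common_to_all`,
  `fx_normalize`) and a deterministic synthetic-fixture generator
  with planted ground truth (`generate_fixtures`).

## Worked example

Design an anti-miR against miR-335-5p, derive its control, and
characterize the R8 conjugate:

```r
library(pnatools)

mir335 <- nucleic_seq("UCAAGAGCAAUAACGAAAAAUGU", name = "miR-335-5p")
reports <- enumerate_candidates(mir335)
reports[[1]]
#> <design_report> miR-335-5p_anti_1_18 (window 1-18)
#>   seed covered: TRUE | self-comp anti/par: 2/2 | PASS

reports[[1]]$candidate$bases
#> [1] "TTTCGTTATTGCTCTTGA"

ctrl <- make_scrambled_control(reports[[1]]$candidate, n_changes = 4,
                               seed = 11, verify_vs = mir335)
ctrl$control$bases
#> [1] "TTTCGCTATTGTTCTGTA"

mass_result(parse_conjugate("H-R8-TTTCGTTATTGCTCTTGA-Gly-NH2"),
            charges = 5:9)
#> H-R8-TTTCGTTATTGCTCTTGA-Gly-NH2: calculated MW 6164.26 g/mol (monoisotopic 6160.73 Da)
#> m/z calculated: 1233.86 [MH5]5+, 1028.38 [MH6]6+, 881.62 [MH7]7+, 771.54 [MH8]8+, 685.93 [MH9]9+
```

The first candidate (miRNA window 1–18) covers the seed region and
passes every screen; its scrambled control differs at exactly four
positions with the same base composition, so parent and control have
bit-identical computed masses (`mass_equal_under_permutation`). The
charge-state list is what ESI-MS deconvolution of the purified
conjugate should reproduce.

Find where the miRNA binds inside a UTR:

```r
fx <- generate_fixtures(seed = 7, utr_len = 200, site_start = 101,
                        mirna_len = 20)
hit <- find_best_site(fx$mirna, fx$utr)[[1]]
hit$target_interval
#> [1] 101 120
```

A command-line front end wrapping the same functions ships at
`system.file("cli", "pnatool.R", package = "pnatools")` with
subcommands `design`, `scramble`, `hybridize`, `mass`, `conserve`,
`fc-report` and `fixtures`.

See the vignette (`vignettes/anti-mir-pna-design.Rmd`) for the model,
its parameters and its limitations.

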