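test_that("candidate enumeration slides one window per position and re-validates", {
  mir <- nucleic_seq(MIR335, name = "miR-335-5p", alphabet = "RNA")
  reports <- enumerate_candidates(mir)
  expect_length(reports, 6L)   # 23 - 18 + 1
  # the window 1-18 candidate is the published anti-miR and covers the seed
  expect_equal(reports[[1]]$candidate$bases, PNA_A335)
  expect_true(reports[[1]]$seed_covered)
  expect_equal(reports[[1]]$mirna_window, c(1L, 18L))
  # every candidate is the reverse complement of its window
  for (r in reports) {
    win <- substr(MIR335, r$mirna_window[1], r$mirna_window[2])
    rc <- to_rna(reverse_complement(
      nucleic_seq(r$candidate$bases, alphabet = "DNA")))$residues
    expect_equal(rc, win)
  }
  # an 18-nt miRNA yields exactly one candidate spanning everything
  one <- enumerate_candidates(nucleic_seq(substr(MIR335, 1, 18),
                                          alphabet = "RNA"))
  expect_length(one, 1L)
  expect_error(enumerate_candidates(nucleic_seq("ACGUACGU",
                                                alphabet = "RNA")),
               "shorter than pna_length")
})

test_that("seed coverage follows the window, not the candidate", {
  mir <- nucleic_seq(MIR335, name = "mir", alphabet = "RNA")
  reports <- enumerate_candidates(mir)
  # window [6,23] starts after seed nt 2 -> not covered
  expect_false(reports[[6]]$seed_covered)
  covered <- vapply(reports, function(r) r$seed_covered, logical(1))
  starts <- vapply(reports, function(r) r$mirna_window[1], integer(1))
  expect_equal(covered, starts <= 2L & starts + 17L >= 8L)
})

test_that("self-complementarity is found by exhaustive offset scan", {
  # self-reverse-complement palindrome pairs over its full length
  expect_equal(self_complementarity(pna_chain("AAAATTTT"))$antiparallel_run,
               8L)
  # homopolymer cannot pair with itself in any register
  sc <- self_complementarity(pna_chain("AAAAAAAA"))
  expect_equal(sc$antiparallel_run, 0L)
  expect_equal(sc$parallel_run, 0L)
  # alternating AT pairs with its own complement at shift 1
  expect_gte(self_complementarity(pna_chain("ATATAT"))$parallel_run, 5L)
  # invariant: antiparallel run is unchanged by reverse-complementing
  set.seed(41)
  for (i in 1:30) {
    p <- pna_chain(paste(sample(c("A", "C", "G", "T"),
                                sample(4:20, 1), replace = TRUE),
                         collapse = ""))
    rc <- pna_chain(to_dna(reverse_complement(
      nucleic_seq(p$bases, alphabet = "DNA")))$residues)
    expect_equal(self_complementarity(p)$antiparallel_run,
                 self_complementarity(rc)$antiparallel_run)
  }
})

test_that("off-target scan matches the brute-force substring oracle", {
  pna <- pna_chain(PNA_A335)
  # constructed hit: transcript carrying the exact 18-nt complement
  set.seed(42)
  emb <- strsplit(random_rna(120)$residues, "")[[1]]
  rc18 <- strsplit(to_rna(reverse_complement(nucleic_seq(
    pna$bases, alphabet = "DNA")))$residues, "")[[1]]
  emb[51:68] <- rc18
  tx <- nucleic_seq(paste(emb, collapse = ""), "embedded", alphabet = "RNA")
  hit <- offtarget_scan(pna, list(tx))
  expect_equal(hit$run, 18L)
  expect_equal(c(hit$start, hit$end), c(51L, 68L))
  # no T in the PNA complement of poly-A -> no run at all
  polyA <- nucleic_seq(strrep("A", 50), "polyA", alphabet = "RNA")
  expect_equal(offtarget_scan(pna_chain("CCGGCCGG"), list(polyA))$run, 0L)
  # empty transcript set is an empty report, not an error
  expect_equal(nrow(offtarget_scan(pna, list())), 0L)
  # oracle agreement on random transcripts
  set.seed(43)
  for (i in 1:60) {
    tx <- random_rna(sample(30:120, 1), sprintf("tx%d", i))
    p <- pna_chain(paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                         collapse = ""))
    expect_equal(offtarget_scan(p, list(tx))$run,
                 oracle_offtarget_run(p, tx),
                 label = sprintf("transcript %d", i))
  }
})

test_that("the published scrambled control satisfies the scramble contract", {
  a <- pna_chain(PNA_A335); m <- pna_chain(PNA_A335_MUT)
  expect_equal(base_composition(a), base_composition(m))
  expect_equal(base_composition(a), c(A = 2L, C = 3L, G = 3L, T = 10L))
  diff_pos <- which(strsplit(a$bases, "")[[1]] != strsplit(m$bases, "")[[1]])
  expect_equal(diff_pos, c(4L, 8L, 13L, 17L))
})

test_that("the scramble generator is seeded, composition-preserving and exact in distance", {
  pna <- pna_chain(PNA_A335)
  mir <- nucleic_seq(MIR335, alphabet = "RNA")
  out1 <- make_scrambled_control(pna, 4L, seed = 7L, verify_vs = mir)
  out2 <- make_scrambled_control(pna, 4L, seed = 7L, verify_vs = mir)
  expect_identical(out1$control$bases, out2$control$bases)  # deterministic
  expect_equal(base_composition(out1$control), base_composition(pna))
  expect_equal(sum(strsplit(out1$control$bases, "")[[1]] !=
                     strsplit(pna$bases, "")[[1]]), 4L)
  expect_lte(out1$residual_run, 8L)
  # different seeds explore different controls (not a constant output)
  outs <- vapply(1:10, function(s)
    make_scrambled_control(pna, 4L, seed = s)$control$bases, character(1))
  expect_gt(length(unique(outs)), 1L)
  # infeasible input fails loudly
  expect_error(make_scrambled_control(pna_chain("AAAAAAAA"), 4L),
               "infeasible")
})

test_that("validate_design aggregates all criteria", {
  mir <- nucleic_seq(MIR335, name = "mir", alphabet = "RNA")
  rep1 <- validate_design(pna_chain(PNA_A335), mir)
  expect_true(rep1$passes[["length"]])
  expect_true(rep1$passes[["seed"]])
  expect_true(rep1$passes[["offtarget"]])   # empty transcript set
  # a designed self-complementary 18-mer fails the self screen
  hairpin <- pna_chain("AAAAAAAAATTTTTTTTT")
  rep2 <- validate_design(hairpin, mir)
  expect_false(rep2$passes[["self_comp"]])
  expect_false(rep2$passes[["all"]])
  # off-target threshold trips when a transcript holds the full complement
  emb <- nucleic_seq(paste0(strrep("G", 20), substr(MIR335, 1, 18),
                            strrep("G", 20)), "tx", alphabet = "RNA")
  rep3 <- validate_design(pna_chain(PNA_A335), mir, transcripts = list(emb))
  expect_false(rep3$passes[["offtarget"]])
  tab <- design_report_table(list(rep1, rep2, rep3))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$pass_all, c(rep1$passes[["all"]], FALSE, FALSE))
})

test_that("scrambling never changes conjugate mass (cross-module invariant)", {
  pna <- pna_chain(PNA_A335)
  parent <- conjugate(pna, n_term_peptide = "RRRRRRRR", c_term_spacer = "G")
  for (s in 1:5) {
    ctrl <- make_scrambled_control(pna, 4L, seed = s)$control
    scr <- conjugate(ctrl, n_term_peptide = "RRRRRRRR", c_term_spacer = "G")
    expect_true(mass_equal_under_permutation(parent, scr))
    expect_identical(conjugate_mw(parent), conjugate_mw(scr))
  }
})
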