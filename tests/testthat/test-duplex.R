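test_that("gapless pairing reproduces the anti-miR / mutant contrast", {
  site <- reverse_complement(to_rna(pna_chain(PNA_A335)))
  # parent: exact reverse complement by construction -> all 18 paired
  perfect <- pair_gapless(pna_chain(PNA_A335), site)
  expect_equal(perfect$counts$n_paired, 18L)
  expect_equal(percent_complementarity(perfect$counts), 1.0)
  # scrambled control: mismatches exactly at the four permuted positions
  mut <- pair_gapless(pna_chain(PNA_A335_MUT), site)
  expect_equal(mut$counts$n_paired, 14L)
  expect_equal(setdiff(1:18, mut$duplex$pairs$query_pos), c(4L, 8L, 13L, 17L))
  # derived independently: positions where the two 18-mers differ
  expect_equal(which(strsplit(PNA_A335, "")[[1]] !=
                       strsplit(PNA_A335_MUT, "")[[1]]),
               c(4L, 8L, 13L, 17L))
  # nothing pairs in a homo-oligomer opposition
  none <- pair_gapless(nucleic_seq("AAAA", alphabet = "RNA"),
                       nucleic_seq("AAAA", alphabet = "RNA"))
  expect_equal(none$counts$n_paired, 0L)
  expect_error(pair_gapless(nucleic_seq("AAA", alphabet = "RNA"),
                            nucleic_seq("AAAA", alphabet = "RNA")),
               "equal length")
})

test_that("percent complementarity is the paired fraction of the query", {
  ct <- structure(list(n_paired = 20L, query_len = 23L),
                  class = "bond_counts")
  expect_equal(percent_complementarity(ct), 20 / 23, tolerance = 1e-12)
  expect_equal(round(100 * percent_complementarity(ct), 1), 87.0)
  ct$n_paired <- 0L
  expect_equal(percent_complementarity(ct), 0)
  expect_error(percent_complementarity(
    structure(list(n_paired = 0L, query_len = 0L), class = "bond_counts")),
    "positive")
})

test_that("bond counts conserve and pairing maps are antiparallel monotone", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:25, 1)
    q <- random_rna(n); s <- random_rna(n)
    res <- pair_gapless(q, s, allow_wobble = sample(c(TRUE, FALSE), 1))
    ct <- res$counts
    expect_equal(ct$n_au + ct$n_gc + ct$n_gu, ct$n_paired)
    expect_lte(ct$n_paired, ct$query_len)
    p <- res$duplex$pairs
    if (nrow(p) >= 2) {
      expect_true(all(diff(p$query_pos) > 0))
      expect_true(all(diff(p$target_pos) < 0))
    }
    expect_false(any(duplicated(p$query_pos)))
    expect_false(any(duplicated(p$target_pos)))
  }
})

test_that("find_best_site recovers a planted perfect site at exact coordinates", {
  set.seed(31)
  short <- random_rna(20, "short")
  lc <- strsplit(random_rna(200)$residues, "")[[1]]
  lc[101:120] <- strsplit(reverse_complement(short)$residues, "")[[1]]
  long <- nucleic_seq(paste(lc, collapse = ""), "long", alphabet = "RNA")
  hits <- find_best_site(short, long)
  expect_equal(hits[[1]]$target_interval, c(101L, 120L))
  expect_equal(nrow(hits[[1]]$duplex$pairs), 20L)
  # score of the perfect duplex is the sum of per-class rewards
  ct <- bond_counts(hits[[1]]$duplex)
  expect_equal(hits[[1]]$score, 3 * ct$n_gc + 2 * ct$n_au + 1 * ct$n_gu)
})

test_that("gapless DP agrees with the exhaustive window oracle (200 instances)", {
  set.seed(32)
  for (i in 1:200) {
    L <- sample(5:40, 1)
    n <- sample(2:min(10, L), 1)
    long <- random_rna(L, "long")
    short <- random_rna(n, "short")
    wobble <- i %% 2 == 0
    ora <- oracle_best_window(short, long, wobble = wobble)
    hits <- find_best_site(short, long,
                           duplex_scoring(allow_wobble = wobble),
                           gapless = TRUE)
    expect_equal(hits[[1]]$score, ora$score,
                 label = sprintf("instance %d score", i))
  }
})

test_that("ties break to the smallest target start coordinate", {
  # two identical perfect sites; the left one must win
  short <- nucleic_seq("ACGU", alphabet = "RNA", name = "s")
  rc <- reverse_complement(short)$residues
  long <- nucleic_seq(paste0("UUU", rc, "UUU", rc, "UUU"),
                      alphabet = "RNA", name = "l")
  hits <- find_best_site(short, long, gapless = TRUE, k = 2L)
  expect_equal(hits[[1]]$target_interval[1], 4L)
  expect_equal(hits[[2]]$target_interval[1], 11L)
})

test_that("perfect-duplex score is monotone in query length and top-k sites never overlap", {
  set.seed(33)
  prev <- 0
  base <- random_rna(30, "base")
  for (n in 3:30) {
    q <- nucleic_seq(substr(base$residues, 1, n), alphabet = "RNA")
    h <- find_best_site(q, reverse_complement(q), gapless = TRUE)
    expect_gte(h[[1]]$score, prev)
    prev <- h[[1]]$score
  }
  long <- random_rna(300, "long")
  short <- random_rna(8, "short")
  hits <- find_best_site(short, long, k = 5L)
  iv <- t(vapply(hits, `[[`, integer(2), "target_interval"))
  if (nrow(iv) >= 2) {
    ord <- order(iv[, 1])
    expect_true(all(iv[ord[-1], 1] > iv[ord[-nrow(iv)], 2]))
  }
})

test_that("bulged sites are found and beat gapless opposition when warranted", {
  # target = revcomp of query with one extra base inserted mid-site:
  # the gapped DP should pair all query bases around a 1-nt target bulge
  set.seed(34)
  q <- random_rna(16, "q")
  rc <- strsplit(reverse_complement(q)$residues, "")[[1]]
  with_bulge <- paste(c(rc[1:8], "A", rc[9:16]), collapse = "")
  long <- nucleic_seq(paste0("GGGGG", with_bulge, "GGGGG"),
                      alphabet = "RNA", name = "l")
  hits <- find_best_site(q, long)
  expect_equal(nrow(hits[[1]]$duplex$pairs), 16L)
  expect_equal(hits[[1]]$target_interval, c(6L, 22L))
  gapless <- find_best_site(q, long, gapless = TRUE)
  expect_gt(hits[[1]]$score, gapless[[1]]$score)
})

test_that("duplex rendering marks pairs, wobbles and gaps correctly", {
  q <- nucleic_seq("ACGU", alphabet = "RNA")
  h <- pair_gapless(q, reverse_complement(q))
  lines <- render_duplex(h$duplex)
  expect_length(lines, 3L)
  expect_equal(lines[2], "   ||||   ")
  # one GU wobble -> exactly one ':'
  wob <- pair_gapless(nucleic_seq("GAAA", alphabet = "RNA"),
                      nucleic_seq("UUUU", alphabet = "RNA"),
                      allow_wobble = TRUE)
  marks <- render_duplex(wob$duplex)[2]
  expect_equal(lengths(regmatches(marks, gregexpr(":", marks))), 1L)
  # all-mismatch duplex -> blank marks line
  none <- pair_gapless(nucleic_seq("AAAA", alphabet = "RNA"),
                       nucleic_seq("AAAA", alphabet = "RNA"))
  expect_match(render_duplex(none$duplex)[2], "^ +$")
})

test_that("site-hit tables flatten hits with 1-based coordinates", {
  short <- nucleic_seq("ACGUACGU", alphabet = "RNA")
  long <- nucleic_seq(paste0("AAAA", reverse_complement(short)$residues,
                             "AAAA"), alphabet = "RNA")
  tab <- site_hit_table(find_best_site(short, long))
  expect_equal(tab$start, 5L)
  expect_equal(tab$end, 12L)
  expect_equal(tab$percent_complementarity, 1.0)
  expect_equal(nrow(site_hit_table(list())), 0L)
})
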