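# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's own DP / scan code paths:
# the window oracle scores by direct character comparison, the
# substring oracle searches with fixed-string matching.

RNA <- c("A", "C", "G", "U")

random_rna <- function(n, name = "r") {
  nucleic_seq(paste(sample(RNA, n, replace = TRUE), collapse = ""),
              name = name, alphabet = "RNA")
}

# complement of RNA-letter characters, by table lookup
ocomp <- function(ch) c(A = "U", C = "G", G = "C", U = "A")[ch]

# is (a, b) a pair? returns "WC_GC"/"WC_AU"/"GU"/NA
opair <- function(a, b, wobble) {
  s <- paste0(sort(c(a, b)), collapse = "")
  if (s == "CG") return("WC_GC")
  if (s == "AU") return("WC_AU")
  if (s == "GU" && wobble) return("GU")
  NA_character_
}

# Exhaustive gapless window scan: best full-length opposition score of
# `short` within `long` under the given rewards. Returns list(score,
# start) with ties to the smallest start.
oracle_best_window <- function(short, long, reward_gc = 3, reward_au = 2,
                               reward_gu = 1, wobble = TRUE) {
  qc <- strsplit(chartr("T", "U", short$residues), "")[[1]]
  tc <- strsplit(chartr("T", "U", long$residues), "")[[1]]
  n <- length(qc); L <- length(tc)
  rew <- c(WC_GC = reward_gc, WC_AU = reward_au, GU = reward_gu)
  best <- -Inf; best_start <- NA_integer_
  for (w in seq_len(L - n + 1L)) {
    s <- 0
    for (i in seq_len(n)) {
      cls <- opair(qc[i], tc[w + n - i], wobble)
      if (!is.na(cls)) s <- s + rew[[cls]]
    }
    if (s > best) { best <- s; best_start <- w }
  }
  list(score = best, start = best_start)
}

# Longest exact complementary stretch between a PNA and a transcript
# in either orientation, by fixed-string search over all PNA
# substrings (longest first).
oracle_offtarget_run <- function(pna, tx) {
  pc <- strsplit(chartr("T", "U", pna$bases), "")[[1]]
  txt <- chartr("T", "U", tx$residues)
  n <- length(pc)
  for (len in n:1) {
    for (a in seq_len(n - len + 1L)) {
      sub <- pc[a:(a + len - 1L)]
      anti <- paste(rev(ocomp(sub)), collapse = "")
      par <- paste(ocomp(sub), collapse = "")
      if (grepl(anti, txt, fixed = TRUE) || grepl(par, txt, fixed = TRUE))
        return(len)
    }
  }
  0L
}

# The four synthesized conjugates and their printed characterization
# values (average MW in g/mol).
PRINTED_CONJUGATES <- data.frame(
  name = c("a335", "a335_MUT", "a96", "a183"),
  descriptor = c("H-R8-TTTCGTTATTGCTCTTGA-Gly-NH2",
                 "H-R8-TTTAGTTCTTGCGCTTTA-Gly-NH2",
                 "H-R8-AAATGTGCTAGTGCCAAA-Gly-NH2",
                 "H-R8-AATTCTACCAGTGCCATA-Gly-NH2"),
  mw = c(6164.30, 6164.30, 6234.36, 6145.31),
  stringsAsFactors = FALSE)

# 18-mer anti-miR against miR-335-5p and its scrambled control
PNA_A335 <- "TTTCGTTATTGCTCTTGA"
PNA_A335_MUT <- "TTTAGTTCTTGCGCTTTA"
# mature miR-335-5p: reverse complement of the anti-miR covers nt 1-18
MIR335 <- "UCAAGAGCAAUAACGAAAAAUGU"
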