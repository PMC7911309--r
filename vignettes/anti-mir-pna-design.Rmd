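---
title: "Designing and characterizing anti-miRNA peptide nucleic acids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and characterizing anti-miRNA peptide nucleic acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnatools)
```

## The problem

Peptide nucleic acids (PNAs) are uncharged DNA analogues built on an
N-(2-aminoethyl)glycine backbone. Written N-terminus to C-terminus,
they hybridize to complementary RNA by Watson–Crick pairing, with the
N-terminus conventionally opposing the RNA 3' end (the antiparallel
geometry). A PNA complementary to a mature microRNA — an anti-miR —
sequesters that miRNA and de-represses its target mRNAs; conjugating
an octaarginine (R8) peptide at the N-terminus drives cellular uptake.

`pnatools` implements the desk work around such a molecule: choosing
the anti-miR sequence, screening it, deriving a mass-matched scrambled
control, locating and scoring the miRNA's binding site in a 3'-UTR,
quantifying how conserved that site is across species, and predicting
the conjugate's mass spectrum for quality control after synthesis.

## Anti-miR design

A candidate anti-miR of length $k$ against a mature miRNA of length
$n$ is the T-lettered reverse complement of one of the $n - k + 1$
windows of the miRNA. Every window is enumerated and screened against
four criteria:

* **Length** — default 18 bases, long enough for high-affinity,
  sequence-unique binding and still convenient for large-scale
  solid-phase synthesis.
* **Seed coverage** — the window should contain miRNA nucleotides 2–8,
  the seed region, which is the primary determinant of target
  recognition; an anti-miR that occludes the seed blocks function most
  effectively. The seed interval is a parameter (`seed_start`,
  `seed_end`), defaulting to the standard 2–8 definition.
* **Self-complementarity** — a PNA that pairs with itself (hairpins or
  duplex dimers) hybridizes poorly. Both orientations matter for PNAs,
  which unlike DNA can also bind parallel; the screen slides the chain
  against a reversed copy (antiparallel) and an unreversed copy
  (parallel) over every register and records the longest contiguous
  complementary run. Runs longer than `max_self_comp_run` (default 3)
  fail. The threshold is this package's operational choice; "lack of
  self-complementarity" has no universal numeric definition.
* **Off-target complementarity** — the longest exact Watson–Crick
  stretch between the candidate and each transcript in a screening
  set, in either binding orientation, must not exceed
  `max_offtarget_run` (default 12). This is an exact, deterministic
  substring scan rather than a heuristic seeded alignment: at PNA
  scale (≤ 20-mers against transcript sets) the exact scan is cheap
  and reproducible. `export_candidates_fasta()` writes candidates out
  for an external BLAST run when genome-scale screening is wanted.

```{r design}
mir335 <- nucleic_seq("UCAAGAGCAAUAACGAAAAAUGU", name = "miR-335-5p")
reports <- enumerate_candidates(mir335)
design_report_table(reports)[, c("bases", "window_start", "window_end",
                                 "seed_covered", "pass_all")]
```

The window 1–18 candidate, `TTTCGTTATTGCTCTTGA`, covers the seed and
passes all screens.

## Scrambled controls

The control for an anti-miR experiment should be a molecule with
identical chemistry and mass that no longer hybridizes. The generator
permutes the bases at exactly `n_changes` positions (default 4) —
never substituting, so the base multiset and hence the conjugate mass
are unchanged — and accepts a candidate only if its longest residual
complementary run against the target miRNA is at most
`max_residual_run` (default 8, i.e. less than half the chain). The
search is bounded rejection sampling (default 10,000 draws),
deterministic given its seed; a homopolymer input, which admits no
distinct permutation, raises an infeasibility error rather than
looping. The residual-run threshold is exposed because one may want
either a minimal-residual-pairing control or merely a
four-changes control; the default enforces the former.

```{r scramble}
ctrl <- make_scrambled_control(pna_chain("TTTCGTTATTGCTCTTGA"),
                               n_changes = 4, seed = 11,
                               verify_vs = mir335)
ctrl$control$bases
ctrl$changed_positions
```

## Duplex model and site finding

Two views of a duplex are provided, because two different questions
are asked of it.

**Gapless full-length pairing** (`pair_gapless()`) opposes position
$i$ of the query to position $L+1-i$ of an equal-length site and
classifies every opposition as A:U, G:C, G:U wobble, or mismatch. This
is the pairing-diagram view: it answers "how many of the miRNA's
nucleotides engage this site", summarized by
`percent_complementarity()` = paired / query length. A 20-of-23
pairing, for instance, is the fraction 20/23 = 0.8696 — the package
reports the exact fraction and leaves rounding to presentation.

**Site finding** (`find_best_site()`) answers "where in a long
sequence does a short one bind best". It is a semi-global dynamic
program: the short strand is engaged over its full length (as a miRNA
is when its site is evaluated), the window on the long strand is
free, and bulges on either strand pay an affine penalty. Scoring is
additive per pair — defaults G:C = +3, A:U = +2, G:U = +1, mismatch 0,
gap open −4, gap extend −2 — an intentionally transparent model, not
a nearest-neighbor free-energy calculation; the numbers encode only
the relative stability ordering G:C > A:U > G:U and a bulge cost
exceeding any single pair reward. Tools that minimize a true
hybridization free energy answer the same algorithmic question with a
physical objective; no equivalence with any of them is claimed, and
this is the package's main known limitation for ranking
near-equal-affinity sites.

With bulges disabled (`gapless = TRUE`) the DP score of a window
equals the plain sum of pair rewards over the full opposition, which
is what the test suite exploits: an exhaustive window-scan oracle must
agree with the DP on every random instance. Ties between
equal-scoring sites break to the smallest target start coordinate;
the top-k sites are taken greedily with overlapping windows discarded,
so output is deterministic. G:U wobble is on by default (RNA:RNA) and
off in `pair_gapless()` (PNA:RNA duplexes are evaluated strict
Watson–Crick, and bond-class reports for them count only AU and GC).

```{r site}
fx <- generate_fixtures(seed = 7, utr_len = 200, site_start = 101,
                        mirna_len = 20)
hit <- find_best_site(fx$mirna, fx$utr)[[1]]
hit$target_interval
cat(render_duplex(hit$duplex), sep = "\n")
```

## Conservation scoring

A binding site that matters tends to be conserved. Given an
already-aligned set of orthologous UTR segments (alignment
construction is out of scope — rows come from an aligned FASTA),
`column_identity()` scores each column as the fraction of
non-reference rows identical to the reference (human, by convention
the first row), and `site_conservation()` averages that over a boxed
site interval. Gaps and ambiguity characters count as mismatches —
the strictest, most easily testable rule; a column-majority metric
would be an alternative convention, and the to-reference definition
is declared as this package's. Identity to a reference is a
descriptive statistic, not a substitution-model-based conservation
score.

## Conjugate mass and ESI series

The mass module is table-driven: residue masses are computed from
elemental compositions (the aeg-PNA unit bearing each
nucleobase-acetyl side chain; the 20 standard amino-acid residues)
under a declared atomic-mass table — IUPAC 2021 average weights and
lightest-isotope monoisotopic masses — with N-terminal H and a
C-terminal NH2 (amide, from Rink-amide resin) or OH (free acid) cap.
The conjugate MW is the linear sum, so permuting PNA bases provably
cannot change it: a scrambled control is mass-matched by construction,
and `mass_equal_under_permutation()` checks exactly that.

The electrospray charge series follows $m/z = (M + n \cdot m_{H^+})/n$
with the proton at 1.00728 Da; a hydrogen-atom carrier (1.008) is
selectable since deconvolution software conventions differ. Average
mass is the convention for multi-kDa species on quadrupole
instruments, and is what `mass_result()` uses for the series; rounding
to two decimals happens only at presentation.

```{r mass}
res <- mass_result(parse_conjugate("H-R8-TTTCGTTATTGCTCTTGA-Gly-NH2"),
                   charges = 5:9)
res
```

## The synthetic-fixture generator

`generate_fixtures()` builds, from one seed, a coherent synthetic
study: a random mature miRNA (default 23 nt, the typical mature
length); a 3'-UTR (default 740 nt, a realistic short UTR) with the
miRNA's exact reverse complement embedded at a known position
(default 501); a 13-row ortholog alignment of the site region
(reference plus twelve species, matching a typical mammalian ortholog
panel) mutated per row at rate 0.1 — a mid-range divergence that
leaves the site recognizable; and a 451-row fold-change table drawn
from planted bucket proportions defaulting to
(0.865, 0.04, 0.047, 0.048) — a miRNome in which roughly 13.5% of
miRNAs respond to a treatment. Every planted fact is recorded in a
truth manifest, so each analysis can be validated against known
ground truth.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: real UTR sites are rarely perfect
complements (the planted site is, so site *recovery* is tested, not
site *discovery* under partial complementarity); real ortholog
alignments contain indels, not only substitutions; and real
fold-change tables have correlated, count-derived noise rather than
independent uniform draws within buckets. The generator validates the
machinery, not biological effect sizes.

## Fold-change bucketing and list intersection

`classify_fold_changes()` buckets a fold-change table (treated over
untreated, > 0) at a two-fold threshold: up-regulated when
fc ≥ 2, down-regulated when 1/fc ≥ 2, with down-regulation split at
1/fc = 3 into moderate (1/fc in [2, 3]) and strong (1/fc > 3). The
ratio-direction convention (down-regulation measured as 1/fc) and the
boundary rule (a value exactly at the modulation threshold counts as
modulated) are declared choices, both configurable.
`common_to_all()` intersects three identifier lists order-stably —
the standard move for nominating a regulator shared between a
differential list, a disease-association list and a target-prediction
list. `fx_normalize()` converts a fluorescence quench trace to
percent variation from the value at iodide addition,
$F_x(t) = 100\,(F_t - F_o)/F_o$.

## Numerical and scale choices

* All coordinates in user-facing output are 1-based inclusive;
  ambiguity codes are rejected at parse time so pairing is always
  defined.
* The DP is quadratic time and memory in pure R; problem sizes here
  (≤ 25-nt queries in multi-kb UTRs) run in milliseconds. The
  property suites use 200 random DP instances (targets ≤ 40 nt) and
  100 random 500-nt transcripts for the off-target oracle — large
  enough to exercise every branch, small enough to keep the whole
  suite under half a minute.
* Scramble and fixture generation restore the caller's RNG state;
  determinism is per explicit seed argument, never global.
* Printed masses elsewhere may differ from this package's by small
  fractions of a dalton depending on the atomic-weight table a
  vendor's software pins; the table here is explicit, versioned
  metadata, and swappable.
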