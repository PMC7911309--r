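## Anti-miR PNA design engine: sliding-window candidate enumeration
## against a mature miRNA, self-complementarity screening (antiparallel
## and parallel), off-target complementary-run scanning across
## transcript sets, and composition-preserving scrambled-control
## generation.

#' Design criteria for anti-miR PNAs
#'
#' The screening thresholds applied to every candidate:
#' an 18-mer length (convenient for large-scale solid-phase synthesis),
#' coverage of the miRNA seed region (nucleotides 2-8, the primary
#' determinant of target recognition, so that the anti-miR blocks it),
#' lack of self-complementarity in both antiparallel and parallel
#' orientation (self-pairing PNAs aggregate and hybridize poorly), and
#' no long exact complementary stretch in any screened transcript
#' (off-target antisense potential).
#'
#' @param pna_length Candidate length in bases.
#' @param seed_start,seed_end Seed interval on the miRNA, 1-based.
#' @param max_self_comp_run Longest tolerated self-complementary run;
#'   runs of `max_self_comp_run + 1` or more fail the screen.
#' @param max_offtarget_run Longest tolerated exact complementary run
#'   against any screened transcript.
#' @param scramble_changes Number of positions permuted when deriving a
#'   scrambled control.
#' @return A `design_criteria` list.
#' @export
design_criteria <- function(pna_length = 18L, seed_start = 2L,
                            seed_end = 8L, max_self_comp_run = 3L,
                            max_offtarget_run = 12L,
                            scramble_changes = 4L) {
  stopifnot(pna_length >= 1L, seed_start >= 1L, seed_end >= seed_start,
            max_self_comp_run >= 0L, max_offtarget_run >= 0L,
            scramble_changes >= 0L)
  if (pna_length < seed_end - seed_start + 1L)
    stop("pna_length is shorter than the seed span")
  structure(list(pna_length = as.integer(pna_length),
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 max_self_comp_run = as.integer(max_self_comp_run),
                 max_offtarget_run = as.integer(max_offtarget_run),
                 scramble_changes = as.integer(scramble_changes)),
            class = "design_criteria")
}

## T-lettered reverse complement of a miRNA window -> pna_chain
.window_to_pna <- function(mirna, start, end, name) {
  win <- substr(mirna$residues, start, end)
  win_seq <- nucleic_seq(win, alphabet = mirna$alphabet)
  pna_chain(to_dna(reverse_complement(win_seq))$residues, name = name)
}

#' Enumerate candidate anti-miR PNAs along a miRNA
#'
#' Slides a window of `criteria$pna_length` along the mature miRNA and
#' emits, for each window, the T-lettered reverse complement as a
#' candidate PNA (N-terminus opposite the window's 3' end), then
#' validates it against all criteria via [validate_design].
#'
#' @param mirna A [nucleic_seq] (the mature miRNA, 5'->3').
#' @param criteria A [design_criteria].
#' @param transcripts Optional list of [nucleic_seq] for the off-target
#'   screen (empty by default).
#' @return List of `design_report` objects, one per window
#'   (`length(mirna) - pna_length + 1` in total).
#' @export
enumerate_candidates <- function(mirna, criteria = design_criteria(),
                                 transcripts = list()) {
  stopifnot(inherits(mirna, "nucleic_seq"))
  n <- length(mirna)
  k <- criteria$pna_length
  if (n < k)
    stop("miRNA (", n, " nt) is shorter than pna_length (", k, ")")
  lapply(seq_len(n - k + 1L), function(w) {
    cand <- .window_to_pna(mirna, w, w + k - 1L,
                           sprintf("%s_anti_%d_%d", mirna$name, w,
                                   w + k - 1L))
    validate_design(cand, mirna, transcripts, criteria,
                    mirna_window = c(w, w + k - 1L))
  })
}

## longest run of TRUE in a logical vector (0 if none)
.longest_run <- function(x) {
  if (length(x) == 0L || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Self-complementarity of a PNA chain
#'
#' Exhaustive offset scan of the chain against a copy of itself in both
#' orientations. In the antiparallel geometry position i of one copy
#' faces position c-i of the other (all register constants c are
#' scanned); in the parallel geometry position i faces position i+d
#' (all shifts d are scanned). The reported value per orientation is
#' the longest contiguous run of Watson-Crick complementary
#' oppositions over all registers.
#'
#' @param pna A [pna_chain].
#' @return List with `antiparallel_run` and `parallel_run` (integers).
#' @examples
#' self_complementarity(pna_chain("AAAATTTT"))  # antiparallel 8
#' @export
self_complementarity <- function(pna) {
  stopifnot(inherits(pna, "pna_chain"))
  ch <- .rna_chars(pna)
  n <- length(ch)
  anti <- 0L
  for (cc in 2:(2L * n)) {
    i <- max(1L, cc - n):min(n, cc - 1L)
    j <- cc - i
    anti <- max(anti,
                .longest_run(.pair_class_vec(ch[i], ch[j], FALSE) != "NONE"))
  }
  par <- 0L
  for (d in seq_len(n - 1L)) {
    i <- 1L:(n - d)
    par <- max(par,
               .longest_run(.pair_class_vec(ch[i], ch[i + d], FALSE) != "NONE"))
  }
  list(antiparallel_run = as.integer(anti), parallel_run = as.integer(par))
}

## Longest common substring length (and location in b) between two
## character vectors, via the classic O(nm) suffix-match DP.
.lcs_run <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L)
    return(list(len = 0L, a_end = NA_integer_, b_end = NA_integer_))
  prev <- integer(m)
  best <- 0L; a_end <- NA_integer_; b_end <- NA_integer_
  for (i in seq_len(n)) {
    cur <- integer(m)
    hit <- a[i] == b
    cur[hit] <- c(0L, prev)[which(hit)] + 1L
    mx <- if (any(hit)) max(cur) else 0L
    if (mx > best) {
      best <- mx
      b_end <- which.max(cur)
      a_end <- i
    }
    prev <- cur
  }
  list(len = best, a_end = a_end, b_end = b_end)
}

#' Scan transcripts for complementary stretches to a PNA
#'
#' For each transcript, finds the longest contiguous stretch over which
#' the PNA is exactly Watson-Crick complementary to the transcript in
#' either binding orientation: antiparallel (the reverse complement of
#' the PNA occurs in the transcript) or parallel (the positionwise
#' complement occurs). This is the deterministic stand-in for a BLAST
#' screen of "minimal length of complementary sequences";
#' [export_candidates_fasta] provides the hand-off for an external
#' BLAST run instead.
#'
#' @param pna A [pna_chain].
#' @param transcripts List of [nucleic_seq].
#' @return data.frame with one row per transcript: `transcript`, `run`
#'   (longest complementary stretch, 0 if none), `start`, `end`
#'   (1-based inclusive location on the transcript, NA if `run` is 0),
#'   `orientation` (`"antiparallel"` or `"parallel"`).
#' @export
offtarget_scan <- function(pna, transcripts) {
  stopifnot(inherits(pna, "pna_chain"))
  if (length(transcripts) == 0L)
    return(data.frame(transcript = character(), run = integer(),
                      start = integer(), end = integer(),
                      orientation = character()))
  pc <- .rna_chars(pna)
  n <- length(pc)
  anti_probe <- .complement_chars(rev(chartr("U", "T", pc)), "RNA")
  anti_probe <- chartr("T", "U", anti_probe)   # revcomp, RNA letters
  par_probe <- chartr("T", "U", .complement_chars(chartr("U", "T", pc), "RNA"))
  rows <- lapply(transcripts, function(tx) {
    stopifnot(inherits(tx, "nucleic_seq"))
    tc <- .rna_chars(tx)
    a <- .lcs_run(anti_probe, tc)
    p <- .lcs_run(par_probe, tc)
    if (p$len > a$len) {
      data.frame(transcript = tx$name, run = p$len,
                 start = if (p$len) p$b_end - p$len + 1L else NA_integer_,
                 end = if (p$len) p$b_end else NA_integer_,
                 orientation = "parallel")
    } else {
      data.frame(transcript = tx$name, run = a$len,
                 start = if (a$len) a$b_end - a$len + 1L else NA_integer_,
                 end = if (a$len) a$b_end else NA_integer_,
                 orientation = "antiparallel")
    }
  })
  do.call(rbind, rows)
}

#' Base composition of a PNA chain
#'
#' @param pna A [pna_chain].
#' @return Named integer vector with counts of A, C, G, T.
#' @export
base_composition <- function(pna) {
  stopifnot(inherits(pna, "pna_chain"))
  ch <- strsplit(pna$bases, "")[[1]]
  vapply(c(A = "A", C = "C", G = "G", T = "T"),
         function(b) sum(ch == b), integer(1))
}

#' Generate a composition-preserving scrambled control
#'
#' Derives a control PNA from a parent by permuting the bases at
#' exactly `n_changes` positions (never substituting), so the base
#' multiset — and hence the conjugate mass — is unchanged while the
#' Hamming distance to the parent is exactly `n_changes`. Candidates
#' are drawn by seeded rejection sampling; each draw picks `n_changes`
#' positions and a derangement-style permutation of their bases, and is
#' accepted only if all picked positions actually change and, when
#' `verify_vs` is supplied, the control's longest complementary run
#' against that target does not exceed `max_residual_run` (suppressing
#' residual hybridization).
#'
#' @param pna Parent [pna_chain].
#' @param n_changes Number of positions that must differ (default 4).
#' @param seed Integer RNG seed; the search is deterministic given it.
#' @param verify_vs Optional [nucleic_seq]: the target (e.g. the miRNA)
#'   the control must no longer hybridize to.
#' @param max_residual_run Acceptance threshold for the longest
#'   complementary run against `verify_vs` (default 8).
#' @param max_attempts Rejection-sampling budget before declaring the
#'   constraint infeasible.
#' @return List with `control` (a [pna_chain]), `changed_positions`,
#'   `hamming`, `composition_preserved`, `residual_run` (NA when
#'   `verify_vs` is absent), and `attempts`.
#' @export
make_scrambled_control <- function(pna, n_changes = 4L, seed = 1L,
                                   verify_vs = NULL,
                                   max_residual_run = 8L,
                                   max_attempts = 10000L) {
  stopifnot(inherits(pna, "pna_chain"), n_changes >= 2L)
  ch <- strsplit(pna$bases, "")[[1]]
  n <- length(ch)
  if (n_changes > n)
    stop("n_changes exceeds chain length")
  if (length(unique(ch)) == 1L)
    stop("infeasible: homopolymer chain has no distinct permutation")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    pos <- sample.int(n, n_changes)
    perm <- sample(n_changes)
    cand <- ch
    cand[pos] <- ch[pos][perm]
    if (sum(cand != ch) != n_changes) next
    ctrl <- pna_chain(paste(cand, collapse = ""),
                      name = paste0(pna$name, "_scr"))
    residual <- NA_integer_
    if (!is.null(verify_vs)) {
      residual <- offtarget_scan(ctrl, list(verify_vs))$run
      if (residual > max_residual_run) next
    }
    return(list(control = ctrl,
                changed_positions = sort(pos),
                hamming = n_changes,
                composition_preserved =
                  identical(base_composition(ctrl), base_composition(pna)),
                residual_run = residual,
                attempts = attempt))
  }
  stop("infeasible: no scrambled control satisfying the constraints ",
       "found in ", max_attempts, " attempts")
}

#' Validate a candidate PNA against all design criteria
#'
#' Aggregates the screens: length, seed coverage, self-complementarity
#' in both orientations, and the off-target run per transcript. A
#' candidate passes overall iff every individual screen passes.
#'
#' @param pna Candidate [pna_chain].
#' @param mirna The targeted [nucleic_seq] miRNA.
#' @param transcripts List of [nucleic_seq] for the off-target screen.
#' @param criteria A [design_criteria].
#' @param mirna_window Optional 1-based window on the miRNA the
#'   candidate is the reverse complement of; located automatically when
#'   omitted (NA window if the candidate matches no window).
#' @return A `design_report` with fields `candidate`, `mirna_window`,
#'   `seed_covered`, `self_comp_antiparallel`, `self_comp_parallel`,
#'   `offtarget` (data.frame), `composition`, and `passes` (named
#'   logical vector with overall `all`).
#' @export
validate_design <- function(pna, mirna, transcripts = list(),
                            criteria = design_criteria(),
                            mirna_window = NULL) {
  stopifnot(inherits(pna, "pna_chain"), inherits(mirna, "nucleic_seq"))
  k <- length(pna)
  if (is.null(mirna_window)) {
    probe <- to_rna(reverse_complement(to_dna(
      nucleic_seq(pna$bases, alphabet = "DNA"))))$residues
    hit <- regexpr(probe, chartr("T", "U", toupper(mirna$residues)),
                   fixed = TRUE)
    mirna_window <- if (hit > 0) c(as.integer(hit),
                                   as.integer(hit) + k - 1L)
                    else c(NA_integer_, NA_integer_)
  }
  seed_covered <- !is.na(mirna_window[1]) &&
    mirna_window[1] <= criteria$seed_start &&
    mirna_window[2] >= criteria$seed_end
  sc <- self_complementarity(pna)
  ot <- offtarget_scan(pna, transcripts)
  passes <- c(
    length = (k == criteria$pna_length),
    seed = seed_covered,
    self_comp = (sc$antiparallel_run <= criteria$max_self_comp_run &&
                   sc$parallel_run <= criteria$max_self_comp_run),
    offtarget = (nrow(ot) == 0L || all(ot$run <= criteria$max_offtarget_run))
  )
  passes <- c(passes, all = all(passes))
  structure(list(candidate = pna, mirna_window = mirna_window,
                 seed_covered = seed_covered,
                 self_comp_antiparallel = sc$antiparallel_run,
                 self_comp_parallel = sc$parallel_run,
                 offtarget = ot,
                 composition = base_composition(pna),
                 passes = passes),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s (window %s-%s)\n", x$candidate$name,
              x$mirna_window[1], x$mirna_window[2]))
  cat(sprintf("  seed covered: %s | self-comp anti/par: %d/%d | %s\n",
              x$seed_covered, x$self_comp_antiparallel,
              x$self_comp_parallel,
              if (x$passes[["all"]]) "PASS" else "FAIL"))
  invisible(x)
}

#' Flatten design reports to a data frame
#'
#' @param reports List of `design_report` objects (or a single one).
#' @return One row per candidate, TSV-ready.
#' @export
design_report_table <- function(reports) {
  if (inherits(reports, "design_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    data.frame(candidate = r$candidate$name, bases = r$candidate$bases,
               window_start = r$mirna_window[1],
               window_end = r$mirna_window[2],
               seed_covered = r$seed_covered,
               self_comp_antiparallel = r$self_comp_antiparallel,
               self_comp_parallel = r$self_comp_parallel,
               max_offtarget_run = if (nrow(r$offtarget)) max(r$offtarget$run)
                                   else NA_integer_,
               pass_length = r$passes[["length"]],
               pass_seed = r$passes[["seed"]],
               pass_self_comp = r$passes[["self_comp"]],
               pass_offtarget = r$passes[["offtarget"]],
               pass_all = r$passes[["all"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export candidate PNAs as DNA-lettered FASTA for external screening
#'
#' Writes the candidates (T-lettered, N->C as 5'->3') to FASTA so they
#' can be screened with an external alignment tool such as BLAST.
#'
#' @param reports List of `design_report` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_candidates_fasta <- function(reports, path) {
  if (inherits(reports, "design_report")) reports <- list(reports)
  seqs <- lapply(reports, function(r)
    nucleic_seq(r$candidate$bases, name = r$candidate$name,
                alphabet = "DNA"))
  write_fasta(seqs, path)
}
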