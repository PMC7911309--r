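## Antiparallel duplex modeling: gapless pairing maps, bond-class
## counts, percent complementarity, and a semi-global dynamic program
## that locates the best binding site of a short strand within a long
## one (the miRNA-in-UTR problem).

#' Duplex scoring parameters
#'
#' Additive scoring for intermolecular antiparallel duplexes. Rewards
#' are per formed pair by bond class; bulges (unopposed bases on either
#' strand) pay an affine penalty; an opposed non-pairing position
#' (mismatch) scores `mismatch` (0 by default, i.e. tolerated but not
#' rewarded). This is a deliberately simple additive model, not a
#' nearest-neighbor free-energy model: it captures the site-finding
#' contract (where does a short strand bind best in a long one) without
#' claiming thermodynamic accuracy.
#'
#' @param reward_gc,reward_au,reward_gu Per-pair rewards.
#' @param mismatch Score of an opposed, non-pairing position.
#' @param gap_open,gap_extend Affine bulge penalties (negative).
#' @param allow_wobble Recognize G:U pairs. Default `TRUE`, the RNA:RNA
#'   convention; set `FALSE` for strict Watson-Crick (PNA:RNA).
#' @return A `duplex_scoring` parameter list.
#' @export
duplex_scoring <- function(reward_gc = 3, reward_au = 2, reward_gu = 1,
                           mismatch = 0, gap_open = -4, gap_extend = -2,
                           allow_wobble = TRUE) {
  stopifnot(reward_gc > 0, reward_au > 0, reward_gu >= 0,
            gap_open <= 0, gap_extend <= 0)
  structure(list(reward_gc = reward_gc, reward_au = reward_au,
                 reward_gu = reward_gu, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 allow_wobble = allow_wobble),
            class = "duplex_scoring")
}

.class_reward <- function(cls, scoring) {
  r <- c(WC_GC = scoring$reward_gc, WC_AU = scoring$reward_au,
         GU = scoring$reward_gu, NONE = scoring$mismatch)
  unname(r[cls])
}

.new_duplex_alignment <- function(query, target, alignment, target_window) {
  pairs <- alignment[!is.na(alignment$class) & alignment$class != "NONE",
                     c("query_pos", "target_pos", "class")]
  rownames(pairs) <- NULL
  structure(list(query = query, target = target, pairs = pairs,
                 target_window = target_window, alignment = alignment),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex_alignment> %s vs %s [target %d..%d], %d pairs\n",
              x$query$name, x$target$name,
              x$target_window[1], x$target_window[2], nrow(x$pairs)))
  cat(render_duplex(x), sep = "\n")
  invisible(x)
}

#' Count bond classes of a duplex
#'
#' @param duplex A `duplex_alignment`.
#' @return A `bond_counts` list: `n_au`, `n_gc`, `n_gu`, `n_paired`
#'   (their sum) and `query_len`.
#' @export
bond_counts <- function(duplex) {
  stopifnot(inherits(duplex, "duplex_alignment"))
  cls <- duplex$pairs$class
  out <- list(n_au = sum(cls == "WC_AU"),
              n_gc = sum(cls == "WC_GC"),
              n_gu = sum(cls == "GU"))
  out$n_paired <- out$n_au + out$n_gc + out$n_gu
  out$query_len <- length(duplex$query)
  structure(out, class = "bond_counts")
}

#' @export
print.bond_counts <- function(x, ...) {
  cat(sprintf("<bond_counts> %d/%d paired (%d AU/UA, %d CG/GC, %d GU)\n",
              x$n_paired, x$query_len, x$n_au, x$n_gc, x$n_gu))
  invisible(x)
}

#' Gapless antiparallel pairing of two equal-length strands
#'
#' Opposes position i of the query (5'->3', or N->C for a PNA) to
#' position L+1-i of the site (5'->3') and classifies every opposed
#' pair. This is the full-length pairing diagram used to report, e.g.,
#' how many of a miRNA's 23 nucleotides engage a target site.
#'
#' @param query A [nucleic_seq] or [pna_chain].
#' @param target_site A [nucleic_seq] of the same length.
#' @param allow_wobble Recognize G:U wobble pairs (default `FALSE`:
#'   strict Watson-Crick, the PNA:RNA convention; set `TRUE` for
#'   RNA:RNA duplexes).
#' @return List with `duplex` (a `duplex_alignment`) and `counts`
#'   (a `bond_counts`).
#' @export
pair_gapless <- function(query, target_site, allow_wobble = FALSE) {
  qc <- .rna_chars(query)
  tc <- .rna_chars(target_site)
  if (length(qc) != length(tc))
    stop("pair_gapless: query (", length(qc), ") and site (", length(tc),
         ") must be equal length")
  n <- length(qc)
  cls <- .pair_class_vec(qc, tc[n:1], allow_wobble)
  aln <- data.frame(query_pos = seq_len(n), target_pos = n:1, class = cls,
                    stringsAsFactors = FALSE)
  qseq <- if (inherits(query, "pna_chain")) to_rna(query) else query
  tseq <- if (inherits(target_site, "nucleic_seq")) target_site
          else nucleic_seq(paste(tc, collapse = ""), alphabet = "RNA")
  dup <- .new_duplex_alignment(qseq, tseq, aln, c(1L, n))
  list(duplex = dup, counts = bond_counts(dup))
}

#' Fraction of the query engaged in base pairs
#'
#' @param counts A `bond_counts`.
#' @return `n_paired / query_len`, a fraction in `[0, 1]`.
#' @examples
#' # 20 of 23 miRNA nucleotides paired:
#' percent_complementarity(structure(list(n_paired = 20, query_len = 23),
#'                                   class = "bond_counts"))
#' @export
percent_complementarity <- function(counts) {
  stopifnot(inherits(counts, "bond_counts") ||
              (is.list(counts) && !is.null(counts$n_paired)))
  if (counts$query_len == 0) stop("query_len must be positive")
  counts$n_paired / counts$query_len
}

## Semi-global Gotoh DP over query (fully consumed) vs a reversed
## target segment (window local). Returns NULL if no alignment, else
## list(score, alignment df, target_window) in ORIGINAL target coords.
## seg_chars: RNA chars of the target segment 5'->3'; seg_offset:
## original position of seg_chars[1] minus 1.
.dp_one_segment <- function(qc, seg_chars, seg_offset, scoring) {
  n <- length(qc)
  tc <- rev(seg_chars)                 # reversed: query and index j co-advance
  L <- length(tc)
  NEG <- -1e18
  rew <- matrix(NEG, n, L)
  cls_m <- matrix("NONE", n, L)
  for (i in seq_len(n)) {
    cls <- .pair_class_vec(rep(qc[i], L), tc, scoring$allow_wobble)
    cls_m[i, ] <- cls
    rew[i, ] <- .class_reward(cls, scoring)
  }
  M <- matrix(NEG, n, L); Ix <- matrix(NEG, n, L); Iy <- matrix(NEG, n, L)
  iy_scan <- function(i) {             # left-to-right within row i
    if (L < 2) return()
    for (j in 2:L)
      Iy[i, j] <<- max(M[i, j - 1] + scoring$gap_open,
                       Iy[i, j - 1] + scoring$gap_extend)
  }
  M[1, ] <- rew[1, ]
  iy_scan(1)
  if (n >= 2) {
    for (i in 2:n) {
      prev <- pmax(M[i - 1, ], Ix[i - 1, ], Iy[i - 1, ])
      if (L >= 2)
        M[i, 2:L] <- rew[i, 2:L] + prev[1:(L - 1)]
      Ix[i, ] <- pmax(M[i - 1, ] + scoring$gap_open,
                      Ix[i - 1, ] + scoring$gap_extend)
      iy_scan(i)
    }
  }
  ends <- M[n, ]
  best <- max(ends)
  if (best <= NEG / 2) return(NULL)
  j_end <- max(which(ends == best))    # largest reversed j = smallest start
  # traceback
  i <- n; j <- j_end; state <- "M"
  path <- list()
  repeat {
    if (state == "M") {
      path[[length(path) + 1L]] <- c(i, j, 1L)   # 1 = opposed
      if (i == 1L) break
      tgt <- M[i, j] - rew[i, j]
      prevs <- c(M = M[i - 1, j - 1], Ix = Ix[i - 1, j - 1],
                 Iy = Iy[i - 1, j - 1])
      state <- names(prevs)[which(abs(prevs - tgt) < 1e-9)][1]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ix") {                   # query base i bulged
      path[[length(path) + 1L]] <- c(i, NA, 2L)
      from_m <- M[i - 1, j] + scoring$gap_open
      state <- if (abs(Ix[i, j] - from_m) < 1e-9) "M" else "Ix"
      i <- i - 1L
    } else {                                      # target base j bulged
      path[[length(path) + 1L]] <- c(NA, j, 3L)
      from_m <- M[i, j - 1] + scoring$gap_open
      state <- if (abs(Iy[i, j] - from_m) < 1e-9) "M" else "Iy"
      j <- j - 1L
    }
  }
  path <- rev(path)
  to_orig <- function(jj) seg_offset + (L + 1L - jj)   # reversed -> original
  aln <- data.frame(
    query_pos = vapply(path, function(p) p[1], numeric(1)),
    target_pos = vapply(path, function(p)
      if (is.na(p[2])) NA_real_ else to_orig(p[2]), numeric(1)),
    class = NA_character_, stringsAsFactors = FALSE)
  opposed <- vapply(path, function(p) p[3] == 1L, logical(1))
  if (any(opposed)) {
    qi <- aln$query_pos[opposed]
    ji <- vapply(path[opposed], function(p) p[2], numeric(1))
    aln$class[opposed] <- cls_m[cbind(qi, ji)]
  }
  tp <- aln$target_pos[!is.na(aln$target_pos)]
  list(score = best, alignment = aln,
       target_window = c(min(tp), max(tp)))
}

#' Find the best binding sites of a short strand in a long one
#'
#' Dynamic program over intermolecular antiparallel duplexes. The short
#' strand (a miRNA, or an anti-miR PNA) is engaged over its full
#' length; the window on the long strand (a 3'-UTR) is free. Opposed
#' non-pairing positions score `scoring$mismatch`; bulges on either
#' strand pay affine penalties. No intramolecular structure is
#' considered. With bulges disabled (`gapless = TRUE`) the DP score of
#' a site equals the plain sum of pair rewards over the full-length
#' opposition of the short strand to that window.
#'
#' Returns the top `k` non-overlapping sites, greedily: the best-scoring
#' site is accepted, its window masked, and the search repeated. Ties
#' on score are broken toward the smallest target start coordinate.
#'
#' @param short,long [nucleic_seq] (or [pna_chain]) objects;
#'   `length(short) <= length(long)`.
#' @param scoring A [duplex_scoring].
#' @param k Maximum number of non-overlapping sites to report.
#' @param gapless Disallow bulges entirely.
#' @return List of site hits, each with `target_interval` (1-based
#'   inclusive on the long strand), `score`, and `duplex`
#'   (a `duplex_alignment`).
#' @export
find_best_site <- function(short, long, scoring = duplex_scoring(),
                           k = 1L, gapless = FALSE) {
  qc <- .rna_chars(short)
  tc <- .rna_chars(long)
  if (length(qc) == 0L || length(tc) == 0L)
    stop("find_best_site: empty sequence")
  if (length(qc) > length(tc))
    stop("find_best_site: short strand is longer than the long one")
  if (gapless) {
    scoring$gap_open <- -1e15
    scoring$gap_extend <- -1e15
  }
  qseq <- if (inherits(short, "pna_chain")) to_rna(short) else short
  tseq <- long
  L <- length(tc)
  masked <- rep(FALSE, L)
  hits <- list()
  for (rep_i in seq_len(k)) {
    # contiguous unmasked segments long enough to host the query window
    r <- rle(!masked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- NULL
    for (s in which(r$values)) {
      seg <- .dp_one_segment(qc, tc[starts[s]:ends[s]], starts[s] - 1L,
                             scoring)
      if (is.null(seg)) next
      if (is.null(best) || seg$score > best$score + 1e-9 ||
          (abs(seg$score - best$score) <= 1e-9 &&
             seg$target_window[1] < best$target_window[1]))
        best <- seg
    }
    if (is.null(best)) break
    dup <- .new_duplex_alignment(qseq, tseq, best$alignment,
                                 as.integer(best$target_window))
    hits[[length(hits) + 1L]] <- list(
      target_interval = as.integer(best$target_window),
      score = best$score, duplex = dup)
    masked[best$target_window[1]:best$target_window[2]] <- TRUE
  }
  hits
}

#' Render a duplex as a three-line text diagram
#'
#' Query 5'->3' on top, pairing marks in the middle (`|` Watson-Crick,
#' `:` G:U wobble, space otherwise), target 3'->5' underneath — the
#' conventional orientation for an antiparallel duplex diagram.
#'
#' @param duplex A `duplex_alignment`.
#' @return Character vector of three lines.
#' @export
render_duplex <- function(duplex) {
  stopifnot(inherits(duplex, "duplex_alignment"))
  aln <- duplex$alignment
  qc <- .rna_chars(duplex$query)
  tc <- .rna_chars(duplex$target)
  top <- ifelse(is.na(aln$query_pos), "-", qc[aln$query_pos])
  bot <- ifelse(is.na(aln$target_pos), "-",
                tc[replace(aln$target_pos, is.na(aln$target_pos), 1L)])
  mark <- ifelse(is.na(aln$class) | aln$class == "NONE", " ",
                 ifelse(aln$class == "GU", ":", "|"))
  c(paste0("5'-", paste(top, collapse = ""), "-3'"),
    paste0("   ", paste(mark, collapse = ""), "   "),
    paste0("3'-", paste(bot, collapse = ""), "-5'"))
}

#' Site-hit table
#'
#' Flattens the hits returned by [find_best_site] into a data frame
#' (one row per site, 1-based inclusive coordinates) suitable for TSV
#' export.
#'
#' @param hits List returned by [find_best_site].
#' @return A data.frame with columns `start`, `end`, `score`,
#'   `n_paired`, `n_au`, `n_gc`, `n_gu`, `query_len`,
#'   `percent_complementarity`.
#' @export
site_hit_table <- function(hits) {
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      score = numeric(), n_paired = integer(),
                      n_au = integer(), n_gc = integer(),
                      n_gu = integer(), query_len = integer(),
                      percent_complementarity = numeric()))
  rows <- lapply(hits, function(h) {
    ct <- bond_counts(h$duplex)
    data.frame(start = h$target_interval[1], end = h$target_interval[2],
               score = h$score, n_paired = ct$n_paired, n_au = ct$n_au,
               n_gc = ct$n_gc, n_gu = ct$n_gu, query_len = ct$query_len,
               percent_complementarity = percent_complementarity(ct))
  })
  do.call(rbind, rows)
}
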