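## Sequence and alphabet primitives shared by all other modules.
## Coordinates: internal work is plain 1-based R indexing; every
## user-facing report is 1-based inclusive.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Named nucleic-acid sequence
#'
#' Constructs a validated, case-normalized RNA or DNA sequence. Residues
#' are stored 5'->3' as a single uppercase string. IUPAC ambiguity codes
#' are rejected: the pairing semantics used throughout the package
#' (Watson-Crick plus optional G:U wobble) are only defined over the
#' four unambiguous bases.
#'
#' @param residues Character scalar, residues 5'->3' (case-insensitive).
#' @param name Identifier for the sequence.
#' @param alphabet `"RNA"` or `"DNA"`. If `NULL` (default), inferred:
#'   a sequence containing `U` is RNA, one containing `T` is DNA, and a
#'   sequence with neither defaults to DNA.
#' @return An object of class `nucleic_seq` with fields `name`,
#'   `alphabet` and `residues`.
#' @examples
#' nucleic_seq("ucaagagcaauaacgaaaaaugu", name = "miR-335-5p")
#' @export
nucleic_seq <- function(residues, name = "seq", alphabet = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("\\s", "", residues))
  if (nchar(residues) < 1L)
    stop("sequence '", name, "' is empty; length >= 1 required")
  if (is.null(alphabet)) {
    has_u <- grepl("U", residues, fixed = TRUE)
    has_t <- grepl("T", residues, fixed = TRUE)
    if (has_u && has_t)
      stop("sequence '", name, "' mixes U and T; declare the alphabet")
    alphabet <- if (has_u) "RNA" else "DNA"
  }
  alphabet <- match.arg(alphabet, c("RNA", "DNA"))
  allowed <- if (alphabet == "RNA") RNA_BASES else DNA_BASES
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L)
    stop("sequence '", name, "': illegal ", alphabet, " character '",
         chars[bad[1]], "' at position ", bad[1])
  structure(list(name = name, alphabet = alphabet, residues = residues),
            class = "nucleic_seq")
}

#' @export
print.nucleic_seq <- function(x, ...) {
  cat(sprintf("<nucleic_seq> %s [%s, %d nt]\n  5'-%s-3'\n",
              x$name, x$alphabet, nchar(x$residues), x$residues))
  invisible(x)
}

#' @export
length.nucleic_seq <- function(x) nchar(x$residues)

#' PNA nucleobase chain
#'
#' A peptide nucleic acid sequence written N-terminus to C-terminus in
#' DNA letters (PNAs carry thymine, not uracil). By convention the
#' N-terminus of a PNA corresponds to the 5' end of the equivalent DNA
#' strand, so the anti-miR PNA against a miRNA window is simply the
#' T-lettered reverse complement of that window.
#'
#' @param bases Character scalar over `A`, `C`, `G`, `T` (case-insensitive).
#' @param name Identifier.
#' @return Object of class `pna_chain` with fields `name` and `bases`.
#' @examples
#' pna_chain("TTTCGTTATTGCTCTTGA", name = "PNA-a335")
#' @export
pna_chain <- function(bases, name = "pna") {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(gsub("\\s", "", bases))
  if (nchar(bases) < 1L) stop("PNA chain '", name, "' is empty")
  chars <- strsplit(bases, "")[[1]]
  bad <- which(!chars %in% DNA_BASES)
  if (length(bad) > 0L)
    stop("PNA chain '", name, "': illegal base '", chars[bad[1]],
         "' at position ", bad[1], " (only A/C/G/T)")
  structure(list(name = name, bases = bases), class = "pna_chain")
}

#' @export
print.pna_chain <- function(x, ...) {
  cat(sprintf("<pna_chain> %s [%d bases]\n  N-%s-C\n",
              x$name, nchar(x$bases), x$bases))
  invisible(x)
}

#' @export
length.pna_chain <- function(x) nchar(x$bases)

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Peptide-PNA conjugate
#'
#' The full synthesized molecule: an optional N-terminal peptide (for
#' delivery, typically octaarginine `"RRRRRRRR"`), the PNA chain, an
#' optional C-terminal amino-acid spacer (typically a single glycine
#' from the synthesis resin), and the C-terminal cap chemistry.
#'
#' @param pna A [pna_chain] (or a string coerced to one).
#' @param n_term_peptide One-letter amino-acid string, possibly `""`.
#' @param c_term_spacer One-letter amino-acid string, possibly `""`.
#' @param c_term_cap `"amide"` (Rink-amide resin, C-terminal NH2) or
#'   `"free_acid"` (C-terminal OH).
#' @param name Identifier.
#' @return Object of class `pna_conjugate`.
#' @examples
#' conjugate(pna_chain("TTTCGTTATTGCTCTTGA"),
#'           n_term_peptide = "RRRRRRRR", c_term_spacer = "G")
#' @export
conjugate <- function(pna, n_term_peptide = "", c_term_spacer = "",
                      c_term_cap = c("amide", "free_acid"),
                      name = NULL) {
  if (is.character(pna)) pna <- pna_chain(pna)
  stopifnot(inherits(pna, "pna_chain"))
  c_term_cap <- match.arg(c_term_cap)
  check_aa <- function(s, what) {
    if (nchar(s) == 0L) return(toupper(s))
    s <- toupper(s)
    chars <- strsplit(s, "")[[1]]
    bad <- which(!chars %in% AA_CODES)
    if (length(bad) > 0L)
      stop(what, ": unknown amino-acid code '", chars[bad[1]],
           "' at position ", bad[1])
    s
  }
  structure(list(
    name = if (is.null(name)) pna$name else name,
    n_term_peptide = check_aa(n_term_peptide, "n_term_peptide"),
    pna = pna,
    c_term_spacer = check_aa(c_term_spacer, "c_term_spacer"),
    c_term_cap = c_term_cap
  ), class = "pna_conjugate")
}

#' @export
print.pna_conjugate <- function(x, ...) {
  cat(sprintf("<pna_conjugate> %s\n  %s\n", x$name, format_conjugate(x)))
  invisible(x)
}

.comp_map <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

.complement_chars <- function(chars, alphabet) {
  out <- unname(.comp_map[chars])
  if (alphabet == "RNA") out[out == "T"] <- "U"
  out
}

#' Reverse complement
#'
#' Reverses a sequence and complements every base, staying in the input
#' alphabet (A<->U for RNA, A<->T for DNA, C<->G in both).
#'
#' @param seq A [nucleic_seq].
#' @return A [nucleic_seq] of the same alphabet.
#' @examples
#' reverse_complement(nucleic_seq("ACGT"))
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "nucleic_seq"))
  chars <- rev(strsplit(seq$residues, "")[[1]])
  nucleic_seq(paste(.complement_chars(chars, seq$alphabet), collapse = ""),
              name = paste0(seq$name, "_rc"), alphabet = seq$alphabet)
}

#' Convert between RNA and DNA lettering
#'
#' `to_rna()` substitutes T->U, `to_dna()` U->T; the alphabet flag is
#' updated and length is preserved. Applying the converter to a sequence
#' already in the requested alphabet is a no-op.
#'
#' @param seq A [nucleic_seq], or for convenience a [pna_chain] (treated
#'   as the DNA-lettered strand N->C = 5'->3').
#' @return A [nucleic_seq] in the requested alphabet.
#' @export
to_rna <- function(seq) {
  if (inherits(seq, "pna_chain"))
    seq <- nucleic_seq(seq$bases, name = seq$name, alphabet = "DNA")
  stopifnot(inherits(seq, "nucleic_seq"))
  if (seq$alphabet == "RNA") return(seq)
  nucleic_seq(chartr("T", "U", seq$residues), name = seq$name,
              alphabet = "RNA")
}

#' @rdname to_rna
#' @export
to_dna <- function(seq) {
  stopifnot(inherits(seq, "nucleic_seq"))
  if (seq$alphabet == "DNA") return(seq)
  nucleic_seq(chartr("U", "T", seq$residues), name = seq$name,
              alphabet = "DNA")
}

#' Classify a base pair
#'
#' Classifies an opposed base pair in an antiparallel duplex. U and T
#' are treated as equivalent (PNAs are written with T, miRNAs with U):
#' both arguments are normalized to RNA letters first. G:U wobble pairs
#' are recognized only when `allow_wobble = TRUE`, the convention for
#' RNA:RNA duplexes; PNA:RNA duplexes are evaluated strict Watson-Crick.
#'
#' @param b1,b2 Single base characters (A/C/G/T/U, case-insensitive).
#' @param allow_wobble Logical; recognize G:U as a pair.
#' @return One of `"WC_AU"`, `"WC_GC"`, `"GU"`, `"NONE"`.
#' @examples
#' base_pair_class("A", "U")
#' base_pair_class("G", "U", allow_wobble = TRUE)
#' @export
base_pair_class <- function(b1, b2, allow_wobble = FALSE) {
  norm <- function(b) {
    b <- toupper(b)
    if (identical(b, "T")) b <- "U"
    if (!b %in% RNA_BASES)
      stop("not a nucleic-acid base: '", b, "'")
    b
  }
  b1 <- norm(b1); b2 <- norm(b2)
  pair <- paste0(sort(c(b1, b2)), collapse = "")
  if (pair == "AU") return("WC_AU")
  if (pair == "CG") return("WC_GC")
  if (pair == "GU" && allow_wobble) return("GU")
  "NONE"
}

## Vectorized internal pair classifier over RNA-letter character vectors.
## Returns a character vector in {WC_AU, WC_GC, GU, NONE}.
.pair_class_vec <- function(v1, v2, allow_wobble) {
  key <- paste0(pmin(v1, v2), pmax(v1, v2))
  out <- rep("NONE", length(key))
  out[key == "AU"] <- "WC_AU"
  out[key == "CG"] <- "WC_GC"
  if (allow_wobble) out[key == "GU"] <- "GU"
  out
}

## chars of a nucleic_seq / pna_chain, normalized to RNA letters
.rna_chars <- function(x) {
  s <- if (inherits(x, "pna_chain")) x$bases
       else if (inherits(x, "nucleic_seq")) x$residues
       else if (is.character(x) && length(x) == 1L) toupper(x)
       else stop("expected a nucleic_seq, pna_chain or string")
  strsplit(chartr("T", "U", s), "")[[1]]
}
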