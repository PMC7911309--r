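## File formats and the conjugate-descriptor grammar. FASTA parsing is
## delegated to Biostrings; this layer adds the package's validation
## (unique names, unambiguous alphabet) and converts to nucleic_seq.

#' Read a FASTA file of nucleic-acid sequences
#'
#' Names are the first whitespace-delimited token of each header;
#' residues are case-normalized and validated against the unambiguous
#' RNA/DNA alphabet (ambiguity codes such as `N` are rejected with a
#' position-bearing error).
#'
#' @param path FASTA file path.
#' @param alphabet `"RNA"`, `"DNA"`, or `NULL` to infer per record.
#' @return List of [nucleic_seq] objects.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1])
  out <- lapply(seq_along(set), function(i)
    nucleic_seq(as.character(set[[i]]), name = nm[i], alphabet = alphabet))
  names(out) <- nm
  out
}

#' Write nucleic-acid sequences as wrapped FASTA
#'
#' @param seqs List of [nucleic_seq] (or a single one).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "nucleic_seq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(
    vapply(seqs, function(s) s$residues, character(1)))
  names(set) <- vapply(seqs, function(s) s$name, character(1))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read an aligned FASTA into an ortholog alignment
#'
#' Rows may contain the gap character `-`; all rows must be of equal
#' length.
#'
#' @param path Aligned FASTA path.
#' @param reference Reference row name (default: first record).
#' @return An [ortholog_alignment].
#' @export
read_aligned_fasta <- function(path, reference = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  rows <- toupper(vapply(seq_along(set), function(i)
    as.character(set[[i]]), character(1)))
  names(rows) <- nm
  bad <- regexpr("[^ACGTU-]", rows)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("alignment row '", nm[i], "': illegal character at position ",
         bad[i])
  }
  ortholog_alignment(rows,
                     reference = if (is.null(reference)) nm[1] else reference)
}

#' Parse a conjugate descriptor
#'
#' Accepts the synthesis-report notation
#' `H-<peptide>-<BASES>-<spacer>-NH2` (amide) or `...-OH` (free acid),
#' with poly-residue shorthand (`R8` = eight arginines), three-letter
#' spacer names (`Gly`), and tolerance for underscore/markup variants
#' (`R_8_`, `NH_2_`). The peptide and spacer segments are optional:
#' `H-ACGT-NH2` is a bare amidated PNA.
#'
#' @param text Descriptor string.
#' @return A [conjugate].
#' @examples
#' parse_conjugate("H-R8-TTTCGTTATTGCTCTTGA-Gly-NH2")
#' @export
parse_conjugate <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- gsub("_", "", gsub("\\s", "", text))
  parts <- strsplit(raw, "-", fixed = TRUE)[[1]]
  if (length(parts) < 3L)
    stop("malformed conjugate descriptor '", text,
         "': expected H-...-NH2 or H-...-OH")
  if (toupper(parts[1]) != "H")
    stop("descriptor must start with 'H-' (got '", parts[1], "')")
  cap_tok <- toupper(parts[length(parts)])
  cap <- switch(cap_tok, NH2 = "amide", OH = "free_acid",
                stop("unknown C-terminal cap '", parts[length(parts)], "'"))
  mid <- parts[-c(1L, length(parts))]
  aa3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
           Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
           Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
           Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  expand_peptide <- function(tok) {
    # three-letter code, or one-letter run with repeat counts (R8, GG)
    key <- paste0(toupper(substr(tok, 1, 1)), tolower(substring(tok, 2)))
    if (key %in% names(aa3)) return(unname(aa3[key]))
    out <- ""
    rest <- toupper(tok)
    while (nchar(rest) > 0L) {
      m <- regmatches(rest, regexec("^([A-Z])([0-9]*)", rest))[[1]]
      if (length(m) == 0L || !m[2] %in% AA_CODES)
        stop("unparseable peptide token '", tok, "' in descriptor")
      k <- if (nchar(m[3]) > 0L) as.integer(m[3]) else 1L
      out <- paste0(out, strrep(m[2], k))
      rest <- substring(rest, nchar(m[1]) + 1L)
    }
    out
  }
  is_pna <- grepl("^[ACGTacgt]+$", mid) & nchar(mid) >= 2L
  pna_idx <- which(is_pna)
  if (length(pna_idx) == 0L)
    stop("descriptor '", text, "' contains no PNA base segment")
  pna_idx <- pna_idx[which.max(nchar(mid[pna_idx]))]
  n_pep <- if (pna_idx > 1L)
    paste(vapply(mid[seq_len(pna_idx - 1L)], expand_peptide,
                 character(1)), collapse = "")
    else ""
  c_spc <- if (pna_idx < length(mid))
    paste(vapply(mid[(pna_idx + 1L):length(mid)], expand_peptide,
                 character(1)), collapse = "")
    else ""
  conjugate(pna_chain(toupper(mid[pna_idx])),
            n_term_peptide = n_pep, c_term_spacer = c_spc,
            c_term_cap = cap, name = raw)
}

#' Format a conjugate as a descriptor string
#'
#' Inverse of [parse_conjugate] (up to shorthand: runs of 4 or more
#' identical peptide residues are compacted, e.g. `RRRRRRRR` -> `R8`;
#' a single glycine spacer prints as `Gly`).
#'
#' @param conj A [conjugate].
#' @return Descriptor string.
#' @export
format_conjugate <- function(conj) {
  stopifnot(inherits(conj, "pna_conjugate"))
  compact <- function(s) {
    if (nchar(s) == 0L) return(NULL)
    r <- rle(strsplit(s, "")[[1]])
    paste0(ifelse(r$lengths >= 4L, paste0(r$values, r$lengths),
                  strrep(r$values, r$lengths)), collapse = "")
  }
  spacer <- if (identical(conj$c_term_spacer, "G")) "Gly"
            else compact(conj$c_term_spacer)
  parts <- c("H", compact(conj$n_term_peptide), conj$pna$bases, spacer,
             if (conj$c_term_cap == "amide") "NH2" else "OH")
  paste(parts[!vapply(parts, is.null, logical(1))], collapse = "-")
}

#' Generate a deterministic synthetic fixture bundle
#'
#' Builds, from one seed, the full set of inputs the toolkit consumes,
#' with planted ground truth: a random mature miRNA; a UTR with the
#' miRNA's exact reverse complement embedded at a known position (the
#' planted binding site); an ortholog alignment derived from the UTR
#' site region by per-row point mutation at a fixed rate; and a
#' fold-change table drawn from planted bucket proportions. The truth
#' manifest records everything planted so each analysis can be checked
#' against it.
#'
#' @param seed Integer RNG seed; output is fully determined by the
#'   arguments.
#' @param mirna_len Mature miRNA length (default 23 nt).
#' @param utr_len UTR length (default 740 nt, a typical short 3'-UTR).
#' @param site_start 1-based start of the planted site in the UTR.
#' @param n_ortholog_rows Number of species rows (default 13).
#' @param ortholog_mutation_rate Per-position substitution probability
#'   in non-reference rows (default 0.1).
#' @param fc_n Number of miRNAs in the fold-change table (default 451).
#' @param fc_props Planted proportions for the buckets
#'   (not_modulated, up, down_mid, down_high); default
#'   `c(0.865, 0.04, 0.047, 0.048)`, a miRNome in which ~13.5% of
#'   miRNAs respond to treatment.
#' @param dir Optional directory: when given, the bundle is also
#'   written there (miRNA/UTR/ortholog FASTA, fold-change TSV, truth
#'   manifest JSON).
#' @return List with `mirna`, `utr`, `orthologs`
#'   (an [ortholog_alignment]), `fold_changes` (data.frame `mirna_id`,
#'   `fc`), and `truth` (manifest list).
#' @export
generate_fixtures <- function(seed = 1L, mirna_len = 23L, utr_len = 740L,
                              site_start = 501L, n_ortholog_rows = 13L,
                              ortholog_mutation_rate = 0.1,
                              fc_n = 451L,
                              fc_props = c(0.865, 0.04, 0.047, 0.048),
                              dir = NULL) {
  stopifnot(mirna_len >= 8L, utr_len >= mirna_len,
            n_ortholog_rows >= 2L,
            ortholog_mutation_rate >= 0, ortholog_mutation_rate <= 1,
            abs(sum(fc_props) - 1) < 1e-8, length(fc_props) == 4L)
  if (site_start < 1L || site_start + mirna_len - 1L > utr_len)
    stop("planted site [", site_start, ",", site_start + mirna_len - 1L,
         "] falls outside the UTR (1..", utr_len, ")")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  rna <- c("A", "C", "G", "U")
  mirna_chars <- sample(rna, mirna_len, replace = TRUE)
  mirna <- nucleic_seq(paste(mirna_chars, collapse = ""),
                       name = "mir_synthetic", alphabet = "RNA")
  utr_chars <- sample(rna, utr_len, replace = TRUE)
  site_end <- site_start + mirna_len - 1L
  site_chars <- .complement_chars(rev(mirna_chars), "RNA")
  utr_chars[site_start:site_end] <- site_chars
  utr <- nucleic_seq(paste(utr_chars, collapse = ""),
                     name = "utr_synthetic", alphabet = "RNA")
  # ortholog rows: site region +/- 10 nt of flank, mutated per row
  flank <- 10L
  reg <- max(1L, site_start - flank):min(utr_len, site_end + flank)
  ref_row <- utr_chars[reg]
  rows <- character(n_ortholog_rows)
  mut_positions <- vector("list", n_ortholog_rows)
  rows[1] <- paste(ref_row, collapse = "")
  mut_positions[[1]] <- integer(0)
  for (r in 2:n_ortholog_rows) {
    row <- ref_row
    mut <- which(stats::runif(length(row)) < ortholog_mutation_rate)
    for (p in mut)
      row[p] <- sample(setdiff(rna, row[p]), 1L)
    rows[r] <- paste(row, collapse = "")
    mut_positions[[r]] <- mut
  }
  names(rows) <- c("reference",
                   paste0("species_", seq_len(n_ortholog_rows - 1L)))
  orthologs <- ortholog_alignment(rows, reference = "reference")
  # fold-change table with planted bucket membership
  bucket <- sample(c("not_modulated", "up", "down_mid", "down_high"),
                   fc_n, replace = TRUE, prob = fc_props)
  fc <- vapply(bucket, function(b) switch(b,
    not_modulated = stats::runif(1, 1 / 1.9, 1.9),
    up = stats::runif(1, 2.0, 6.0),
    down_mid = 1 / stats::runif(1, 2.0, 3.0),
    down_high = 1 / stats::runif(1, 3.0001, 8.0)), numeric(1))
  fold_changes <- data.frame(
    mirna_id = sprintf("mir_synth_%03d", seq_len(fc_n)),
    fc = unname(fc))
  truth <- list(seed = seed,
                site_interval = c(site_start, site_end),
                site_region_columns = c(site_start, site_end) - reg[1] + 1L,
                ortholog_mutation_positions = mut_positions,
                planted_buckets = bucket,
                planted_proportions = stats::setNames(
                  fc_props, c("not_modulated", "up", "down_mid",
                              "down_high")))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(mirna, file.path(dir, "mirna.fa"))
    write_fasta(utr, file.path(dir, "utr.fa"))
    set <- Biostrings::BStringSet(rows)
    Biostrings::writeXStringSet(set, file.path(dir, "orthologs.aln.fa"),
                                width = 60L)
    utils::write.table(fold_changes, file.path(dir, "fold_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(mirna = mirna, utr = utr, orthologs = orthologs,
       fold_changes = fold_changes, truth = truth)
}
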