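## Binding-site conservation scoring across orthologous aligned 3'-UTR
## segments: per-column identity to a reference row (human, by
## convention) and mean identity over boxed site intervals.

#' Ortholog alignment container
#'
#' Holds an already-computed multiple alignment of orthologous
#' segments (gap character `-`). Alignment construction itself is out
#' of scope: rows come from an aligned FASTA ([read_aligned_fasta]) or
#' are built directly.
#'
#' @param rows Named character vector of aligned sequences, all equal
#'   length.
#' @param reference Name of the reference row (default: the first).
#' @return An `ortholog_alignment` with `rows`, `reference`, `ncol`.
#' @export
ortholog_alignment <- function(rows, reference = names(rows)[1]) {
  stopifnot(is.character(rows), length(rows) >= 1L,
            !is.null(names(rows)), all(nzchar(names(rows))))
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: row widths ", paste(widths, collapse = ", "))
  if (widths[1] < 1L) stop("alignment has zero columns")
  if (!reference %in% names(rows))
    stop("reference row '", reference, "' not present")
  structure(list(rows = rows, reference = reference,
                 ncol = unname(widths[1])),
            class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf("<ortholog_alignment> %d rows x %d columns (ref: %s)\n",
              length(x$rows), x$ncol, x$reference))
  invisible(x)
}

#' Per-column identity to the reference row
#'
#' At each alignment column, the fraction of non-reference rows whose
#' character equals the reference's. Gaps and ambiguity characters
#' count as mismatches (and a gapped reference position can only be
#' "matched" by nothing, since rows never match a reference gap — a
#' gap-vs-gap column scores 0 by the same rule).
#'
#' @param aln An [ortholog_alignment].
#' @return A `conservation_profile`: `per_column_identity` (numeric in
#'   `[0,1]` per column), `n_rows_compared`, `reference`.
#' @export
column_identity <- function(aln) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(mat) <- names(aln$rows)
  ref <- mat[aln$reference, ]
  others <- mat[setdiff(rownames(mat), aln$reference), , drop = FALSE]
  if (nrow(others) == 0L)
    stop("alignment needs at least one non-reference row")
  ok <- others == matrix(ref, nrow(others), aln$ncol, byrow = TRUE)
  # a gap in either row is never a match
  ok[others == "-"] <- FALSE
  ok[, ref == "-"] <- FALSE
  structure(list(per_column_identity = colMeans(ok),
                 n_rows_compared = nrow(others),
                 reference = aln$reference),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf(
    "<conservation_profile> %d columns, %d rows vs '%s'; mean %.3f\n",
    length(x$per_column_identity), x$n_rows_compared, x$reference,
    mean(x$per_column_identity)))
  invisible(x)
}

#' Mean identity over a binding-site interval
#'
#' @param profile A `conservation_profile`.
#' @param site Length-2 integer vector, 1-based inclusive column
#'   interval.
#' @return Arithmetic mean of the per-column identities in the site.
#' @export
site_conservation <- function(profile, site) {
  stopifnot(inherits(profile, "conservation_profile"),
            length(site) == 2L)
  n <- length(profile$per_column_identity)
  if (site[1] < 1L || site[2] > n || site[1] > site[2])
    stop("site interval [", site[1], ",", site[2],
         "] invalid for ", n, " columns")
  mean(profile$per_column_identity[site[1]:site[2]])
}

#' Text homology bar
#'
#' Renders the per-column identity as a one-character-per-column bar
#' (0-9 deciles, `*` for exactly 1.0), the text analogue of the
#' homology track under a conservation panel.
#'
#' @param profile A `conservation_profile`.
#' @return A single string, one character per column.
#' @export
homology_bar <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  v <- profile$per_column_identity
  ch <- ifelse(v >= 1, "*", as.character(floor(v * 10)))
  paste(ch, collapse = "")
}

#' Conservation profile as a data frame
#'
#' @param profile A `conservation_profile`.
#' @return data.frame with `column` (1-based) and `identity`.
#' @export
conservation_table <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  data.frame(column = seq_along(profile$per_column_identity),
             identity = unname(profile$per_column_identity))
}
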