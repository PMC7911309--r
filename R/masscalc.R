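## Molecular weights of peptide-PNA conjugates and ESI-MS charge-state
## series. Residue masses are derived at table-construction time from
## elemental compositions and a declared atomic-mass table, never
## hard-coded, so the whole mass model is swappable data.

## Atomic masses. Average: IUPAC 2021 standard atomic weights
## (abridged). Monoisotopic: CODATA/AME lightest-isotope masses.
.ATOMIC_MASSES <- list(
  average = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
              S = 32.06),
  monoisotopic = c(C = 12.0, H = 1.00782503, N = 14.00307401,
                   O = 15.99491462, S = 31.97207117)
)

## Elemental compositions of residues (polymer units, i.e. monomer
## minus water). PNA units: N-(2-aminoethyl)glycine backbone bearing
## the nucleobase through a carbonylmethyl linker.
.PNA_RESIDUE_FORMULAS <- list(
  A = c(C = 11, H = 13, N = 7, O = 2),
  C = c(C = 10, H = 13, N = 5, O = 3),
  G = c(C = 11, H = 13, N = 7, O = 3),
  T = c(C = 11, H = 14, N = 4, O = 4)
)

## The 20 standard amino-acid residues.
.AA_RESIDUE_FORMULAS <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  D = c(C = 4, H = 5, N = 1, O = 3),
  E = c(C = 5, H = 7, N = 1, O = 3),
  F = c(C = 9, H = 9, N = 1, O = 1),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  R = c(C = 6, H = 12, N = 4, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2)
)

.formula_mass <- function(formula, atoms) {
  sum(atoms[names(formula)] * formula)
}

#' Residue mass table for conjugate MW calculation
#'
#' Builds the per-residue mass table from elemental compositions and an
#' atomic-mass table, for both average and monoisotopic modes. Terminal
#' adjustments: the N-terminal hydrogen, the C-terminal amide (NH2,
#' from Rink-amide resin synthesis) or free-acid (OH) cap, and the
#' charge-carrier mass for ESI series.
#'
#' @param charge_carrier `"proton"` (1.00728 Da, the [M+nH]n+
#'   convention) or `"hydrogen"` (average H, 1.008): which mass is
#'   added per charge in the ESI series.
#' @return A `mass_table` with elements `pna_residue_masses` and
#'   `aa_residue_masses` (each a list with `average` and `monoisotopic`
#'   named vectors), `terminal_adjustments`, `proton_mass`, and
#'   `atomic_masses` metadata.
#' @export
mass_table <- function(charge_carrier = c("proton", "hydrogen")) {
  charge_carrier <- match.arg(charge_carrier)
  build <- function(formulas, atoms)
    vapply(formulas, .formula_mass, numeric(1), atoms = atoms)
  avg <- .ATOMIC_MASSES$average
  mono <- .ATOMIC_MASSES$monoisotopic
  structure(list(
    pna_residue_masses = list(
      average = build(.PNA_RESIDUE_FORMULAS, avg),
      monoisotopic = build(.PNA_RESIDUE_FORMULAS, mono)),
    aa_residue_masses = list(
      average = build(.AA_RESIDUE_FORMULAS, avg),
      monoisotopic = build(.AA_RESIDUE_FORMULAS, mono)),
    terminal_adjustments = list(
      average = c(n_term_h = avg[["H"]],
                  amide = avg[["N"]] + 2 * avg[["H"]],
                  free_acid = avg[["O"]] + avg[["H"]]),
      monoisotopic = c(n_term_h = mono[["H"]],
                       amide = mono[["N"]] + 2 * mono[["H"]],
                       free_acid = mono[["O"]] + mono[["H"]])),
    proton_mass = if (charge_carrier == "proton") 1.00728 else avg[["H"]],
    charge_carrier = charge_carrier,
    atomic_masses = .ATOMIC_MASSES
  ), class = "mass_table")
}

#' Molecular weight of a peptide-PNA conjugate
#'
#' Sums residue masses over the N-terminal peptide, the PNA chain and
#' the C-terminal spacer, plus the N-terminal hydrogen and the
#' C-terminal cap (NH2 for amide, OH for free acid). Linear in the
#' residues, so permuting PNA bases never changes the mass.
#'
#' @param conj A [conjugate].
#' @param table A [mass_table].
#' @param mode `"average"` (the convention for multi-kDa ESI
#'   deconvolution) or `"monoisotopic"`.
#' @return Mass in g/mol (Da), a numeric scalar.
#' @examples
#' conjugate_mw(parse_conjugate("H-R8-TTTCGTTATTGCTCTTGA-Gly-NH2"))
#' @export
conjugate_mw <- function(conj, table = mass_table(),
                         mode = c("average", "monoisotopic")) {
  stopifnot(inherits(conj, "pna_conjugate"), inherits(table, "mass_table"))
  mode <- match.arg(mode)
  aa_m <- table$aa_residue_masses[[mode]]
  pna_m <- table$pna_residue_masses[[mode]]
  term <- table$terminal_adjustments[[mode]]
  sum_res <- function(s, masses, what) {
    if (nchar(s) == 0L) return(0)
    ch <- strsplit(s, "")[[1]]
    bad <- which(!ch %in% names(masses))
    if (length(bad))
      stop("unknown ", what, " residue '", ch[bad[1]], "'")
    sum(masses[ch])
  }
  sum_res(conj$n_term_peptide, aa_m, "amino-acid") +
    sum_res(conj$pna$bases, pna_m, "PNA") +
    sum_res(conj$c_term_spacer, aa_m, "amino-acid") +
    term[["n_term_h"]] +
    if (conj$c_term_cap == "amide") term[["amide"]] else term[["free_acid"]]
}

#' ESI multiply-protonated charge-state series
#'
#' m/z of the [M+nH]n+ ion at each requested charge:
#' `(mw + n * proton_mass) / n`. Values are exact; rounding is left to
#' presentation ([format_mass_result]).
#'
#' @param mw Molecular weight (g/mol).
#' @param charges Integer charges, all >= 1.
#' @param table A [mass_table] (supplies the charge-carrier mass).
#' @return data.frame with columns `charge` and `mz`, decreasing in
#'   `mz` as charge increases.
#' @export
esi_series <- function(mw, charges = 1:12, table = mass_table()) {
  stopifnot(is.numeric(mw), mw > 0)
  charges <- as.integer(charges)
  if (any(charges < 1L)) stop("charges must be >= 1")
  data.frame(charge = charges,
             mz = (mw + charges * table$proton_mass) / charges)
}

#' Full mass characterization of a conjugate
#'
#' @param conj A [conjugate].
#' @param charges Charges for the ESI series.
#' @param table A [mass_table].
#' @return A `mass_result`: `mw_avg`, `mw_mono`, `series` (data.frame
#'   of charge and average-mass m/z).
#' @export
mass_result <- function(conj, charges = 1:12, table = mass_table()) {
  mw_avg <- conjugate_mw(conj, table, "average")
  structure(list(
    name = conj$name,
    mw_avg = mw_avg,
    mw_mono = conjugate_mw(conj, table, "monoisotopic"),
    series = esi_series(mw_avg, charges, table)
  ), class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat(format_mass_result(x), sep = "\n")
  invisible(x)
}

#' Format a mass result the way an MS characterization section prints it
#'
#' Two decimals for MW and m/z.
#'
#' @param x A `mass_result`.
#' @return Character vector of report lines.
#' @export
format_mass_result <- function(x) {
  stopifnot(inherits(x, "mass_result"))
  ser <- sprintf("%.2f [MH%d]%d+", x$series$mz, x$series$charge,
                 x$series$charge)
  c(sprintf("%s: calculated MW %.2f g/mol (monoisotopic %.2f Da)",
            x$name, x$mw_avg, x$mw_mono),
    paste("m/z calculated:", paste(ser, collapse = ", ")))
}

#' Are two conjugates mass-equal by composition?
#'
#' TRUE iff the peptide parts, cap, and PNA base multisets match — in
#' which case the computed masses are bit-identical, which is what
#' makes a scrambled control a true mass-matched control.
#'
#' @param c1,c2 [conjugate] objects.
#' @return Logical scalar.
#' @export
mass_equal_under_permutation <- function(c1, c2) {
  stopifnot(inherits(c1, "pna_conjugate"), inherits(c2, "pna_conjugate"))
  identical(c1$n_term_peptide, c2$n_term_peptide) &&
    identical(c1$c_term_spacer, c2$c_term_spacer) &&
    identical(c1$c_term_cap, c2$c_term_cap) &&
    identical(sort(strsplit(c1$pna$bases, "")[[1]]),
              sort(strsplit(c2$pna$bases, "")[[1]]))
}
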