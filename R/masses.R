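#' Monoisotopic residue masses for the 20 standard amino acids
#'
#' Chain (residue) masses in Da, i.e. the mass each residue contributes to a
#' peptide after loss of water during peptide-bond formation.
#'
#' @format Named numeric vector, one entry per 1-letter residue code.
#' @export
MONOISOTOPIC_RESIDUES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Average residue masses for the 20 standard amino acids
#'
#' @format Named numeric vector, one entry per 1-letter residue code.
#' @export
AVERAGE_RESIDUES <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Mass of the +80 phospho modification (HPO3) in Da
#' @export
PHOSPHO_DELTA <- 79.96633

#' Build a peptide mass table
#'
#' Collects the constants needed for [M+H]+ calculation: per-residue chain
#' masses, the mass of water (restored at the peptide termini), the mass added
#' by protonation, and the phospho modification mass. The default protonation
#' mass is that of a neutral hydrogen atom (1.0078250 Da): peptide-mass
#' fingerprinting software traditionally computes [M+H]+ by adding H rather
#' than a bare proton, i.e. the electron mass is neglected. The difference
#' (0.00055 Da) is visible at the second decimal for some peptides, and the
#' H-atom convention is the one that reproduces published MALDI peptide-mass
#' tables; the bare-proton value 1.007276 can be supplied instead.
#'
#' @param residue_mass named numeric vector of per-residue chain masses;
#'   defaults to [MONOISOTOPIC_RESIDUES]. Supply [AVERAGE_RESIDUES] (with a
#'   matching `water`) for average-mass mode, or any modified copy.
#' @param water mass of water in Da (default monoisotopic, 18.010565).
#' @param proton mass added by protonation in Da (default 1.0078250, the
#'   hydrogen-atom convention; see Details).
#' @param phospho_delta mass of one HPO3 modification in Da.
#' @return An object of class `mass_table`.
#' @examples
#' tab <- mass_table()
#' peptide_mh("FYLQGRCPYGSR", tab)
#' @export
mass_table <- function(residue_mass = MONOISOTOPIC_RESIDUES,
                       water = 18.010565,
                       proton = 1.0078250,
                       phospho_delta = PHOSPHO_DELTA) {
  stopifnot(is.numeric(residue_mass), length(residue_mass) > 0,
            !is.null(names(residue_mass)))
  if (any(residue_mass <= 0) || water <= 0 || proton <= 0 || phospho_delta <= 0)
    stop("all masses in a mass table must be positive")
  if (abs(phospho_delta - 79.97) > 0.01)
    stop("phospho_delta must be within 0.01 Da of 79.97 (HPO3)")
  structure(
    list(residue_mass = residue_mass, water = water, proton = proton,
         phospho_delta = phospho_delta),
    class = "mass_table"
  )
}

#' @export
print.mass_table <- function(x, ...) {
  cat("<mass_table> ", length(x$residue_mass), " residues; water ",
      format(x$water), ", proton ", format(x$proton), ", phospho ",
      format(x$phospho_delta), " Da\n", sep = "")
  invisible(x)
}

#' Monoisotopic [M+H]+ mass of an unmodified peptide
#'
#' Sums per-residue chain masses, restores one water, and adds the
#' protonation mass. Input case is ignored. Cysteines are computed free
#' (no fixed alkylation).
#'
#' @param sequence peptide sequence, 1-letter codes (character scalar or
#'   vector; vectors are computed element-wise).
#' @param table a [mass_table()].
#' @return Numeric vector of [M+H]+ masses in Da, full precision.
#' @examples
#' peptide_mh("CHFIHNPSEDLAAPGHPPVLR")  # 2307.15 at 2 dp
#' @export
peptide_mh <- function(sequence, table = mass_table()) {
  stopifnot(is.character(sequence))
  vapply(toupper(sequence), function(s) {
    if (!nzchar(s)) return(table$water + table$proton)
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!(res %in% names(table$residue_mass)))
    if (length(bad))
      stop("unknown residue code '", res[bad[1]], "' at position ", bad[1])
    sum(table$residue_mass[res]) + table$water + table$proton
  }, numeric(1), USE.NAMES = FALSE)
}

#' [M+H]+ mass of a phosphopeptide
#'
#' Adds `n_phospho` HPO3 mass shifts to the unmodified [M+H]+. The number of
#' phosphates may not exceed the number of phosphorylatable residues
#' (Ser/Thr/Tyr) in the sequence.
#'
#' @inheritParams peptide_mh
#' @param n_phospho number of phosphate groups (integer >= 0).
#' @return [M+H]+ mass in Da.
#' @examples
#' modified_mh("YKTELCRTFSESGR", 1)
#' @export
modified_mh <- function(sequence, n_phospho, table = mass_table()) {
  stopifnot(length(n_phospho) == 1, n_phospho >= 0, n_phospho == round(n_phospho))
  n_sites <- count_sty(sequence)
  if (any(n_phospho > n_sites))
    stop("n_phospho (", n_phospho, ") exceeds the ", min(n_sites),
         " phosphorylatable S/T/Y residues in the sequence")
  peptide_mh(sequence, table) + n_phospho * table$phospho_delta
}

count_sty <- function(sequence) {
  vapply(toupper(sequence),
         function(s) sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("S", "T", "Y")),
         integer(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Display rounding used when comparing against published tables (R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
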