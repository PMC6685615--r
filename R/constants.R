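# Pinned physical constants. All masses are monoisotopic (Da). The atomic
# masses below are the CODATA/AME values commonly used by proteomics search
# engines; they are frozen here so fragment tables are bit-stable across
# platforms and package versions.

#' Monoisotopic atomic masses (Da)
#'
#' Named vector of monoisotopic atomic masses used for all elemental
#' arithmetic in the package (modification deltas, residue masses).
#'
#' @format Named numeric vector (H, C, N, O, S).
#' @export
ATOMIC_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Mass of a proton (Da)
#' @export
PROTON_MASS <- 1.007276

#' Monoisotopic mass of water (Da)
#' @export
WATER_MASS <- 18.010565

# Elemental composition of the 20 amino-acid residues (as incorporated in a
# peptide chain, i.e. minus water).
.RESIDUE_ELEMENTS <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.element_mass <- function(elements) {
  stopifnot(all(names(elements) %in% names(ATOMIC_MASS)))
  sum(ATOMIC_MASS[names(elements)] * as.numeric(elements))
}

#' Monoisotopic residue masses (Da)
#'
#' Masses of the 20 amino-acid residues as chain members (free amino acid
#' minus water), derived from [ATOMIC_MASS] at load time.
#'
#' @format Named numeric vector over the 20 one-letter residue codes.
#' @export
RESIDUE_MASS <- vapply(.RESIDUE_ELEMENTS, .element_mass, numeric(1))

#' One-letter codes of the 20 standard amino acids
#' @export
AA_LETTERS <- names(RESIDUE_MASS)

# Modification-class tokens recognized by the mod-code grammar. Anything
# else is carried through as "other:<token>".
.KNOWN_MOD_CLASSES <- c("p", "ub", "ac", "m1", "m2", "m3", "sm", "ga", "gl")
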