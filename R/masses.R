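# Monoisotopic mass arithmetic for b/y fragment and precursor m/z validation.

# monoisotopic residue masses (Da), 20 standard amino acids
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
PROTON_MASS <- 1.00727646688
WATER_MASS <- 18.010564684

residue_masses <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, names(RESIDUE_MASS))
  if (length(unknown)) {
    irt_error(sprintf("unknown amino acid residue(s): %s",
                      paste(unique(unknown), collapse = ", ")),
              "irtnorm_input_error")
  }
  RESIDUE_MASS[chars]
}

#' Theoretical fragment ion m/z
#'
#' Monoisotopic m/z of a b- or y-series fragment of an unmodified peptide:
#' b_k carries the first k residues plus charge protons; y_k carries the last
#' k residues plus water plus charge protons. Mass conservation holds:
#' b_k + y_(L-k) (singly charged) equals the precursor neutral mass plus two
#' protons.
#'
#' @param sequence unmodified peptide string over the 20-letter alphabet.
#' @param series `"b"` or `"y"`.
#' @param ordinal number of residues in the fragment (1 to sequence length).
#' @param charge positive integer fragment charge.
#' @return Fragment m/z in Thomson.
#' @examples
#' fragment_mz("AGK", "b", 2, 1)  # ~129.066
#' @export
fragment_mz <- function(sequence, series = c("b", "y"), ordinal, charge = 1L) {
  series <- match.arg(series)
  if (charge < 1 || charge != floor(charge)) {
    irt_error("charge must be a positive integer", "irtnorm_input_error")
  }
  masses <- residue_masses(sequence)
  L <- length(masses)
  if (ordinal < 1 || ordinal > L || ordinal != floor(ordinal)) {
    irt_error(sprintf("ordinal must be an integer in [1, %d]", L),
              "irtnorm_input_error")
  }
  neutral <- if (series == "b") {
    sum(masses[seq_len(ordinal)])
  } else {
    sum(masses[(L - ordinal + 1L):L]) + WATER_MASS
  }
  (neutral + charge * PROTON_MASS) / charge
}

#' Theoretical precursor m/z
#'
#' @inheritParams fragment_mz
#' @return Precursor m/z in Thomson.
#' @export
precursor_mz <- function(sequence, charge = 1L) {
  if (charge < 1 || charge != floor(charge)) {
    irt_error("charge must be a positive integer", "irtnorm_input_error")
  }
  (sum(residue_masses(sequence)) + WATER_MASS + charge * PROTON_MASS) / charge
}
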