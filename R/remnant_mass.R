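# Monoisotopic residue masses (Da) and elemental compositions of the 20
# standard amino-acid residues (i.e. amino acid minus water, as found inside
# a peptide chain). Values are the standard unimod/expasy residue masses.
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

AA_COMPOSITION <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0))

#' Monoisotopic mass and composition of a peptide remnant modification
#'
#' Computes the mass added to a modified residue by a conjugated peptide
#' remnant, e.g. the DVFQQQTGG stub that Lys-C/Asp-N digestion of SUMO-2/3
#' leaves on the acceptor lysine. Because the remnant is conjugated through
#' an isopeptide bond (it is not a free peptide), residue masses are summed
#' without adding terminal water.
#'
#' @param remnant_sequence character string over the 20 standard one-letter
#'   amino-acid codes. The empty string gives mass 0.
#' @return list with elements `mass` (monoisotopic Da), `composition`
#'   (named integer vector over C, H, N, O, S) and `formula`
#'   (e.g. `"C41H60N12O15"`).
#' @examples
#' remnant_mass("DVFQQQTGG")$mass   # the SUMO-2/3 remnant, 960.4301 Da
#' remnant_mass("GG")$mass          # the ubiquitin remnant, 114.0429 Da
#' @export
remnant_mass <- function(remnant_sequence) {
  stopifnot(is.character(remnant_sequence), length(remnant_sequence) == 1L)
  if (nchar(remnant_sequence) == 0L) {
    comp <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
    return(list(mass = 0, composition = comp, formula = ""))
  }
  aa <- strsplit(remnant_sequence, "")[[1]]
  bad <- setdiff(aa, names(AA_MONO_MASS))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  mass <- sum(AA_MONO_MASS[aa])
  comp <- Reduce(`+`, AA_COMPOSITION[aa])
  comp <- round(comp)
  storage.mode(comp) <- "integer"
  nonzero <- comp[comp > 0L]
  formula <- paste0(names(nonzero), nonzero, collapse = "")
  list(mass = unname(mass), composition = comp, formula = formula)
}
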