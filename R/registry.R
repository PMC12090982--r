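#' Monosaccharide residue mass registry
#'
#' Holds the monoisotopic residue masses used for all mass arithmetic, plus
#' the physical constants (water, electron) and the cation masses for singly
#' charged adducts. Residue masses are *residue* masses, i.e. the mass of the
#' monosaccharide after loss of one water on glycosidic-bond formation; a free
#' reducing end is restored by adding one water in [neutral_mass()].
#'
#' The default table covers the residue kinds that appear in compositional
#' annotations of enzymatically released N-glycans: hexose (Hex), N-acetyl-
#' hexosamine (HexNAc), deoxyhexose (dHex, i.e. fucose), N-acetylneuraminic
#' acid (NeuAc), N-glycolylneuraminic acid (NeuGc) and pentose (Pent).
#'
#' @param residues Optional named numeric vector of extra (or overriding)
#'   residue monoisotopic masses in Da. Names are residue symbols.
#' @param adducts Optional named numeric vector of extra (or overriding)
#'   adduct cation masses in Da (atomic masses; the electron is subtracted
#'   separately when forming an ion).
#'
#' @return An object of class `glycan_registry`: a list with elements
#'   `residues`, `adducts`, `water`, `electron`.
#'
#' @examples
#' reg <- glycan_registry()
#' reg$residues[["Hex"]]
#' # extend with a custom residue without touching any classification logic
#' reg2 <- glycan_registry(residues = c(Sulf = 79.956815))
#' @export
glycan_registry <- function(residues = NULL, adducts = NULL) {
  res <- c(
    Hex    = 162.052824,
    HexNAc = 203.079373,
    dHex   = 146.057909,
    NeuAc  = 291.095417,
    NeuGc  = 307.090331,
    Pent   = 132.042259
  )
  add <- c(
    H  = 1.00782503207,
    Na = 22.9897692809,
    K  = 38.96370668
  )
  if (!is.null(residues)) {
    stopifnot(is.numeric(residues), !is.null(names(residues)))
    if (any(residues <= 0)) stop("residue masses must be positive")
    res[names(residues)] <- residues
  }
  if (!is.null(adducts)) {
    stopifnot(is.numeric(adducts), !is.null(names(adducts)))
    add[names(adducts)] <- adducts
  }
  structure(
    list(
      residues = res,
      adducts = add,
      water = 18.0105646863,
      electron = 0.00054857990946
    ),
    class = "glycan_registry"
  )
}

#' @export
print.glycan_registry <- function(x, ...) {
  cat("<glycan_registry>\n")
  cat("  residues:", paste(sprintf("%s=%.6f", names(x$residues), x$residues),
                           collapse = ", "), "\n")
  cat("  adducts: ", paste(sprintf("%s=%.6f", names(x$adducts), x$adducts),
                           collapse = ", "), "\n")
  invisible(x)
}
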