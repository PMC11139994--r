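.FATTY_ACIDS <- list(
  palmitic      = "C16H32O2",   # 16:0
  palmitoleic   = "C16H30O2",   # 16:1
  oleic         = "C18H34O2",   # 18:1
  hydroxystearic = "C18H36O3"   # 18:0 with one hydroxyl
)

.FAHFA_FAMILIES <- list(
  PAHSA = list(acyl = "palmitic",    hydroxy = "hydroxystearic"),
  OAHSA = list(acyl = "oleic",       hydroxy = "hydroxystearic"),
  POHSA = list(acyl = "palmitoleic", hydroxy = "hydroxystearic")
)

#' Construct a FAHFA species
#'
#' Builds a fatty-acyl ester of a hydroxy fatty acid from a family name
#' (PAHSA = palmitic / hydroxystearic; OAHSA = oleic / hydroxystearic;
#' POHSA = palmitoleic / hydroxystearic) or from explicit chain formulas.
#' An isotope label (e.g. \code{labelN = 16} for the 13C16 internal
#' standard) is applied to the acyl chain, where commercial standards carry
#' it.
#'
#' @param family Family name, one of the built-ins above, or any label when
#'   \code{acyl} and \code{hydroxy} are given explicitly.
#' @param acyl,hydroxy Formula strings of the free fatty acids (defaults
#'   from the family table).
#' @param labelN Number of labeled atoms on the acyl chain (0 = endogenous).
#' @param labelFrom,labelTo Isotope symbols of the substitution.
#' @return A [FahfaSpecies-class] object.
#' @examples
#' fahfaSpecies("PAHSA")
#' fahfaSpecies("PAHSA", labelN = 16)  # the 13C16 internal standard
#' @export
fahfaSpecies <- function(family, acyl = NULL, hydroxy = NULL, labelN = 0,
                         labelFrom = "C", labelTo = "13C") {
  if (is.null(acyl) || is.null(hydroxy)) {
    fam <- .FAHFA_FAMILIES[[family]]
    if (is.null(fam))
      stop("unknown FAHFA family '", family, "'; built-ins: ",
           paste(names(.FAHFA_FAMILIES), collapse = ", "),
           " (or supply acyl/hydroxy formulas)")
    acyl <- acyl %||% .FATTY_ACIDS[[fam$acyl]]
    hydroxy <- hydroxy %||% .FATTY_ACIDS[[fam$hydroxy]]
  }
  if (is.character(acyl)) acyl <- parseFormula(acyl)
  if (is.character(hydroxy)) hydroxy <- parseFormula(hydroxy)
  new("FahfaSpecies", family = family, acyl = acyl, hydroxy = hydroxy,
      labelN = labelN, labelFrom = labelFrom, labelTo = labelTo)
}

#' Intact (esterified) formula of a FAHFA species
#'
#' The ester condenses the acyl carboxyl with the chain hydroxyl:
#' \code{acyl + hydroxy - H2O}, with any isotope label applied to the acyl
#' chain first.
#'
#' @param species A [FahfaSpecies-class] object.
#' @return A [MolecularFormula-class] of the intact neutral lipid.
#' @export
intactFormula <- function(species) {
  stopifnot(is(species, "FahfaSpecies"))
  (.labeledAcyl(species) + species@hydroxy) - parseFormula("H2O")
}

.labeledAcyl <- function(species) {
  if (species@labelN == 0) return(species@acyl)
  applyIsotopeLabel(species@acyl, species@labelN, species@labelFrom,
                    species@labelTo)
}

setMethod("show", "FahfaSpecies", function(object) {
  lab <- if (object@labelN > 0)
    sprintf(" [%s%d]", object@labelTo, as.integer(object@labelN)) else ""
  cat("FahfaSpecies ", object@family, lab, ": ",
      formulaString(intactFormula(object)), ", [M-H]- ",
      roundMz(adductMz(intactFormula(object), "[M-H]-"), 1), "\n", sep = "")
})

#' Negative-mode MRM transitions for a FAHFA species
#'
#' Catalog of triple-quadrupole transitions used for targeted FAHFA
#' quantification in negative ionization mode. The precursor is the
#' deprotonated intact lipid; the fragment catalog holds three anions: the
#' acyl-chain carboxylate, the hydroxy-fatty-acid carboxylate, and its
#' water-loss ion. Isotope labels propagate to the fragments that contain
#' labeled atoms (the acyl carboxylate, for acyl-chain labels). m/z values
#' are reported at 1 dp, as transition lists print them; collision energies
#' are annotation only.
#'
#' @param species A [FahfaSpecies-class] object.
#' @return data.frame with columns \code{species}, \code{label},
#'   \code{precursor_mz}, \code{fragment_mz}, \code{fragment_kind},
#'   \code{polarity}, \code{collision_energy}.
#' @examples
#' fahfaTransitions(fahfaSpecies("PAHSA"))  # 537.5 -> 255.2, 299.3, 281.2
#' @export
fahfaTransitions <- function(species) {
  stopifnot(is(species, "FahfaSpecies"))
  neg <- adduct("[M-H]-")
  prec <- roundMz(adductMz(intactFormula(species), neg), 1)
  acylLab <- .labeledAcyl(species)
  frags <- c(
    "acyl-carboxylate" = adductMz(acylLab, neg),
    "hydroxy-FA-carboxylate" = adductMz(species@hydroxy, neg),
    "hydroxy-FA-carboxylate-minus-H2O" =
      adductMz(species@hydroxy - parseFormula("H2O"), neg))
  lab <- if (species@labelN > 0)
    sprintf("%s%d", species@labelTo, as.integer(species@labelN)) else ""
  out <- data.frame(
    species = species@family, label = lab,
    precursor_mz = prec, fragment_mz = roundMz(unname(frags), 1),
    fragment_kind = names(frags), polarity = "-",
    collision_energy = NA_real_, row.names = NULL,
    stringsAsFactors = FALSE)
  stopifnot(all(out$precursor_mz > out$fragment_mz))
  out
}

#' Transition table for several FAHFA families
#'
#' Convenience wrapper stacking [fahfaTransitions()] over endogenous
#' species and optional labeled internal standards.
#'
#' @param families Character vector of family names.
#' @param labels Named integer vector: label size per family for the
#'   internal standards to include (e.g. \code{c(PAHSA = 16, OAHSA = 18)}).
#' @return A single stacked transition data.frame.
#' @export
fahfaTransitionTable <- function(families = c("PAHSA", "OAHSA", "POHSA"),
                                 labels = c(PAHSA = 16, OAHSA = 18)) {
  rows <- lapply(families, function(f) fahfaTransitions(fahfaSpecies(f)))
  labs <- lapply(names(labels)[names(labels) %in% families], function(f)
    fahfaTransitions(fahfaSpecies(f, labelN = labels[[f]])))
  do.call(rbind, c(rows, labs))
}
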