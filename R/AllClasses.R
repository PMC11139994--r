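#' @import methods
#' @importFrom stats median rnorm rlnorm runif rpois sd setNames coef fitted
#'   resid var aggregate
#' @importFrom utils read.delim write.table modifyList
NULL

#' MolecularFormula: isotope-resolved elemental composition
#'
#' Holds non-negative counts keyed by isotope-qualified element symbol
#' (\code{"C"}, \code{"13C"}, \code{"H"}, \code{"2H"}, \code{"N"},
#' \code{"15N"}, \code{"O"}, \code{"S"}, ...). Formulas add element-wise
#' with \code{+} and subtract with \code{-} (subtraction errors if an atom
#' is not present). The empty formula has mass 0.
#'
#' @slot counts Named numeric vector of non-negative integer atom counts.
#' @seealso [parseFormula()], [monoisotopicMass()], [formulaString()]
#' @export
setClass("MolecularFormula", representation(counts = "numeric"))

setValidity("MolecularFormula", function(object) {
  cnt <- object@counts
  if (length(cnt) && is.null(names(cnt)))
    return("counts must be named by isotope symbol")
  bad <- setdiff(names(cnt), names(.ISOTOPE_MASSES))
  if (length(bad))
    return(paste0("unknown isotope symbol(s): ", paste(bad, collapse = ", ")))
  if (any(cnt < 0)) return("atom counts must be non-negative")
  if (any(cnt != round(cnt))) return("atom counts must be integers")
  if (anyDuplicated(names(cnt))) return("duplicate isotope symbols in counts")
  TRUE
})

#' Adduct: ionization rule applied to a neutral formula
#'
#' An adduct names atoms gained, atoms lost, and the charge acquired during
#' ionization. Built-in adducts: \code{"[M+H]+"} (add H, charge +1),
#' \code{"[M-H]-"} (remove H, charge -1), and \code{"[M-tBu+H]+"} (net loss
#' of C4H8 from a tert-butyl ester/carbamate, charge +1).
#'
#' @slot name Display name of the adduct.
#' @slot add MolecularFormula of atoms gained.
#' @slot remove MolecularFormula of atoms lost.
#' @slot charge Signed integer charge (never 0).
#' @seealso [adduct()], [adductMz()]
#' @export
setClass("Adduct", representation(
  name = "character", add = "MolecularFormula",
  remove = "MolecularFormula", charge = "numeric"))

setValidity("Adduct", function(object) {
  if (length(object@charge) != 1 || object@charge == 0 ||
      object@charge != round(object@charge))
    return("charge must be a single non-zero integer")
  TRUE
})

#' FahfaSpecies: a fatty-acyl ester of a hydroxy fatty acid
#'
#' A FAHFA is defined by its acyl fatty-acid chain and its hydroxy
#' fatty-acid chain; the intact species is their ester,
#' \code{acyl + hydroxy - H2O}. An optional isotope label (e.g. 13C16 on the
#' palmitic acyl chain of the internal standard) is carried as counts moved
#' from one isotope to another; labels are assumed confined to the acyl
#' chain, matching commercial FAHFA standards. Positional isomer labels
#' (5-/9-/12-) are metadata only and do not change mass.
#'
#' @slot family Family name, e.g. "PAHSA", "OAHSA", "POHSA".
#' @slot acyl MolecularFormula of the free acyl fatty acid.
#' @slot hydroxy MolecularFormula of the free hydroxy fatty acid.
#' @slot labelN Number of atoms isotopically substituted (0 = unlabeled).
#' @slot labelFrom,labelTo Isotope symbols for the substitution.
#' @seealso [fahfaSpecies()], [fahfaTransitions()]
#' @export
setClass("FahfaSpecies", representation(
  family = "character", acyl = "MolecularFormula",
  hydroxy = "MolecularFormula", labelN = "numeric",
  labelFrom = "character", labelTo = "character"))

setValidity("FahfaSpecies", function(object) {
  if (object@labelN < 0) return("labelN must be >= 0")
  if (object@labelN > 0) {
    have <- object@acyl@counts[object@labelFrom]
    if (is.na(have) || have < object@labelN)
      return("acyl chain has fewer atoms than the requested label count")
  }
  TRUE
})

#' GroundTruth: the known state of a simulated competition experiment
#'
#' Per simulated protein: how many peptides and PSMs it contributes, what
#' fraction of its peptides are unique, and its true fractional inhibition
#' in every treatment channel — given either directly as a matrix or via a
#' logistic dose-response (ic50, hill) evaluated at each channel's
#' concentration.
#'
#' @slot proteins data.frame with columns \code{protein}, \code{n_peptides},
#'   \code{psms_per_peptide}, \code{unique_fraction}, and optionally
#'   \code{ic50} (molar) and \code{hill}.
#' @slot inhibition Matrix (protein x treatment channel) of fractional
#'   inhibition in [0, 1], or a 0x0 matrix when ic50 curves are used.
#' @seealso [groundTruth()], [simulateIsobaricPsms()]
#' @export
setClass("GroundTruth", representation(
  proteins = "data.frame", inhibition = "matrix"))

setValidity("GroundTruth", function(object) {
  p <- object@proteins
  need <- c("protein", "n_peptides", "psms_per_peptide", "unique_fraction")
  if (!all(need %in% names(p)))
    return(paste("proteins needs columns:", paste(need, collapse = ", ")))
  if (any(p$n_peptides < 1)) return("n_peptides must be >= 1")
  if (any(p$unique_fraction < 0 | p$unique_fraction > 1))
    return("unique_fraction must lie in [0, 1]")
  if (anyDuplicated(p$protein)) return("duplicate protein accessions")
  inh <- object@inhibition
  if (length(inh)) {
    if (nrow(inh) != nrow(p)) return("inhibition rows must match proteins")
    if (any(inh < 0 | inh > 1)) return("inhibition must lie in [0, 1]")
  } else if (!all(c("ic50", "hill") %in% names(p))) {
    return("either an inhibition matrix or ic50/hill columns are required")
  } else if (any(!is.na(p$ic50) & p$ic50 <= 0)) {
    return("ic50 must be positive")
  }
  TRUE
})

#' NoiseModel: stochastic structure of simulated reporter data
#'
#' Log-normal multiplicative noise for intensities (strictly positive and
#' scale-free, as reporter signals are) and a log-normal reporter noise
#' floor from which per-measurement noise values are drawn; SNR is
#' intensity / noise. An optional per-channel bias models unequal channel
#' loading, which per-channel normalization is designed to remove.
#'
#' @slot psmSigma Log-normal sigma of the per-PSM base abundance spread.
#' @slot channelSigma Log-normal sigma of per-measurement multiplicative
#'   noise.
#' @slot baseMeanlog Mean log intensity of a PSM's base signal.
#' @slot noiseMeanlog,noiseSigma Log-normal parameters of the reporter
#'   noise floor.
#' @slot channelBias Per-channel multiplicative loading factors (length 1
#'   recycles).
#' @seealso [noiseModel()]
#' @export
setClass("NoiseModel", representation(
  psmSigma = "numeric", channelSigma = "numeric", baseMeanlog = "numeric",
  noiseMeanlog = "numeric", noiseSigma = "numeric", channelBias = "numeric"))

setValidity("NoiseModel", function(object) {
  if (object@psmSigma < 0 || object@channelSigma < 0 || object@noiseSigma < 0)
    return("sigmas must be >= 0")
  if (any(object@channelBias <= 0))
    return("channelBias must be strictly positive")
  TRUE
})

#' DoseResponseFit: result of a four-parameter logistic fit
#'
#' Parameters of the variable-slope sigmoidal dose-response model
#' \deqn{y(c) = bottom + (top - bottom) / (1 + 10^{(\log_{10} IC50 -
#' \log_{10} c)\, hill})}
#' fitted by nonlinear least squares on semi-log-transformed data, with
#' diagnostics. A fit that failed to converge, or degenerate input (all
#' responses equal), is returned with \code{converged = FALSE} rather than
#' silently.
#'
#' @slot bottom,top Asymptotes in response units (percent of control).
#' @slot hill Hill slope (dimensionless; sign encodes direction).
#' @slot ic50 Half-maximal concentration, molar.
#' @slot rss Residual sum of squares.
#' @slot converged Logical convergence flag.
#' @slot se Named numeric vector of parameter standard errors (may be
#'   empty).
#' @slot message Diagnostic message for non-converged fits.
#' @seealso [fit4PL()]
#' @export
setClass("DoseResponseFit", representation(
  bottom = "numeric", top = "numeric", hill = "numeric", ic50 = "numeric",
  rss = "numeric", converged = "logical", se = "numeric",
  message = "character"))
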