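#' Monoisotopic atomic mass table
#'
#' Monoisotopic masses (Da) of the isotopes understood by the formula
#' calculator, pinned to CODATA/NIST values at >= 6 decimal places. Plain
#' element symbols denote the most abundant isotope; isotope-qualified
#' symbols (\code{"13C"}, \code{"2H"}, \code{"15N"}, ...) denote specific
#' heavy isotopes used for metabolic or chemical labeling. The table is a
#' package constant and is never fetched at runtime.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @examples
#' isotopeMasses()[["C"]]   # 12 by definition
#' isotopeMasses()[["13C"]] - isotopeMasses()[["C"]]  # ~1.003355
#' @export
isotopeMasses <- function() .ISOTOPE_MASSES

.ISOTOPE_MASSES <- c(
  "H"   = 1.00782503207,
  "2H"  = 2.01410177785,
  "C"   = 12.0,
  "13C" = 13.00335483780,
  "N"   = 14.00307400480,
  "15N" = 15.00010889840,
  "O"   = 15.99491461956,
  "17O" = 16.99913170,
  "18O" = 17.99916104,
  "S"   = 31.97207100,
  "34S" = 33.96786690,
  "P"   = 30.97376163,
  "F"   = 18.99840322,
  "Cl"  = 34.96885268,
  "Br"  = 78.91833710,
  "I"   = 126.90447300,
  "Na"  = 22.98976928,
  "K"   = 38.96370668,
  "Si"  = 27.97692653,
  "Se"  = 79.91652130,
  "Fe"  = 55.93493750
)

# mass of a proton-as-hydrogen: the calculator follows the convention of
# printed "calcd" values, i.e. plain H addition with no electron correction
.MASS_H   <- .ISOTOPE_MASSES[["H"]]
.MASS_H2O <- 2 * .ISOTOPE_MASSES[["H"]] + .ISOTOPE_MASSES[["O"]]
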