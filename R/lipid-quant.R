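#' Default FAHFA internal-standard map
#'
#' PAHSAs are normalized to the 13C16-9-PAHSA spike; OAHSAs to
#' 13C18-12-OAHSA. POHSAs have no labeled standard of their own and default
#' to the 13C16-9-PAHSA spike — an inference, since targeted FAHFA panels
#' spike no POHSA standard; override the map to change it.
#'
#' @return Named character vector mapping family to internal-standard id.
#' @export
defaultStandardMap <- function() {
  c(PAHSA = "13C16-9-PAHSA", POHSA = "13C16-9-PAHSA",
    OAHSA = "13C18-12-OAHSA")
}

#' Internal-standard quantification of MRM peak areas
#'
#' Single-point isotope-dilution quantification:
#' \deqn{amount = \frac{area}{area_{IS}} \times pmol_{IS} / normalizer}
#' per species and sample, assuming a 1:1 response factor between each
#' analyte and its family's isotopologue standard. Samples missing their
#' required spike, or with a zero standard area, are excluded with a log
#' entry rather than quantified.
#'
#' @param measurements data.frame(\code{sample}, \code{species},
#'   \code{family}, \code{area}) of analyte peak areas (>= 0).
#' @param spikes data.frame(\code{sample}, \code{standard},
#'   \code{amount_pmol}, \code{area}) of spiked internal standards.
#' @param samples data.frame(\code{sample}, \code{normalizer},
#'   \code{unit}) — mg protein, g tissue, or mL serum; normalizer > 0.
#' @param standardMap Named map family -> standard id (default
#'   [defaultStandardMap()]).
#' @return data.frame(\code{sample}, \code{species}, \code{family},
#'   \code{amount}, \code{unit}) with unit \code{"pmol/<normalizer
#'   unit>"}; excluded samples in \code{attr(, "excluded")}.
#' @examples
#' m <- data.frame(sample = "s1", species = "9-PAHSA", family = "PAHSA",
#'                 area = 500)
#' sp <- data.frame(sample = "s1", standard = "13C16-9-PAHSA",
#'                  amount_pmol = 10, area = 2000)
#' sm <- data.frame(sample = "s1", normalizer = 0.05, unit = "g")
#' quantifyLipids(m, sp, sm)  # 50 pmol/g
#' @export
quantifyLipids <- function(measurements, spikes, samples,
                           standardMap = defaultStandardMap()) {
  stopifnot(all(measurements$area >= 0), all(samples$normalizer > 0),
            all(measurements$family %in% names(standardMap)))
  out <- NULL
  excluded <- data.frame(sample = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (s in unique(measurements$sample)) {
    meta <- samples[samples$sample == s, , drop = FALSE]
    if (nrow(meta) != 1) {
      excluded <- rbind(excluded,
                        data.frame(sample = s, reason = "missing metadata"))
      next
    }
    m <- measurements[measurements$sample == s, , drop = FALSE]
    sp <- spikes[spikes$sample == s, , drop = FALSE]
    need <- unique(standardMap[m$family])
    isIdx <- match(need, sp$standard)
    if (any(is.na(isIdx)) || any(sp$area[isIdx] <= 0)) {
      bad <- if (any(is.na(isIdx))) "missing internal-standard spike"
             else "zero internal-standard area"
      excluded <- rbind(excluded, data.frame(sample = s, reason = bad))
      next
    }
    isArea <- setNames(sp$area[isIdx], need)
    isAmt <- setNames(sp$amount_pmol[isIdx], need)
    stdOf <- standardMap[m$family]
    amount <- (m$area / isArea[stdOf]) * isAmt[stdOf] / meta$normalizer
    out <- rbind(out, data.frame(
      sample = s, species = m$species, family = m$family,
      amount = unname(amount), unit = paste0("pmol/", meta$unit),
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(sample = character(), species = character(),
                      family = character(), amount = numeric(),
                      unit = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Per-family totals of quantified lipids
#'
#' Sums positional-isomer amounts within each family and sample (isomers
#' share a mass; the total is the family-level readout).
#'
#' @param amounts Output of [quantifyLipids()].
#' @return data.frame(\code{sample}, \code{family}, \code{total},
#'   \code{unit}).
#' @export
familyRollup <- function(amounts) {
  if (!nrow(amounts))
    return(data.frame(sample = character(), family = character(),
                      total = numeric(), unit = character(),
                      stringsAsFactors = FALSE))
  agg <- aggregate(amount ~ sample + family + unit, data = amounts,
                   FUN = sum)
  names(agg)[names(agg) == "amount"] <- "total"
  agg[order(agg$sample, agg$family),
      c("sample", "family", "total", "unit")]
}
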