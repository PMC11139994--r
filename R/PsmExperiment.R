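#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

#' PsmExperiment: PSM-by-channel reporter quantification container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are peptide-spectrum
#' matches and whose columns are isobaric reporter channels. Assays:
#' \code{snr} (always present; reporter intensity / reporter noise), and
#' optionally \code{intensity} and \code{noise}. Row metadata carries
#' \code{spectrum_id}, \code{protein}, \code{peptide}
#' (modification-stripped) and the \code{unique} flag; column metadata is
#' the experiment design (see [experimentDesign()]).
#'
#' @seealso [PsmExperiment()], [simulateIsobaricPsms()],
#'   [proteinCompetition()]
#' @export
setClass("PsmExperiment", contains = "SummarizedExperiment")

setValidity("PsmExperiment", function(object) {
  if (!"snr" %in% assayNames(object)) return("assay 'snr' is required")
  need <- c("spectrum_id", "protein", "peptide", "unique")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    return(paste("rowData needs columns:", paste(miss, collapse = ", ")))
  if (!"role" %in% colnames(colData(object)))
    return("colData needs a 'role' column (control/treatment)")
  if (any(assay(object, "snr") < 0, na.rm = TRUE))
    return("SNR values must be >= 0")
  if (ncol(object) < 1) return("at least one channel is required")
  TRUE
})

#' Build a PsmExperiment
#'
#' @param snr Numeric matrix (PSM x channel) of signal-to-noise ratios.
#' @param rowData data.frame/DataFrame with \code{spectrum_id},
#'   \code{protein}, \code{peptide}, \code{unique}.
#' @param design Experiment design from [experimentDesign()]; its channels
#'   must match \code{colnames(snr)}.
#' @param intensity,noise Optional matrices matching \code{snr}.
#' @return A [PsmExperiment-class] object.
#' @export
PsmExperiment <- function(snr, rowData, design, intensity = NULL,
                          noise = NULL) {
  if (!is.null(colnames(snr)) &&
      !identical(colnames(snr), design$channel))
    stop("snr columns do not match design channels")
  colnames(snr) <- design$channel
  assays <- list(snr = snr)
  if (!is.null(intensity)) assays$intensity <- intensity
  if (!is.null(noise)) assays$noise <- noise
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(rowData),
    colData = DataFrame(design, row.names = design$channel))
  new("PsmExperiment", se)
}

setMethod("show", "PsmExperiment", function(object) {
  d <- psmDesign(object)
  cat("PsmExperiment: ", nrow(object), " PSMs (",
      length(unique(rowData(object)$protein)), " proteins) x ",
      ncol(object), " channels (", sum(d$role == "control"),
      " control)\n", sep = "")
})

#' Define an isobaric experiment design
#'
#' The channel layout of a competition experiment: which channels are
#' vehicle-control replicates and which carry the inhibitor at which molar
#' concentration. At least two control channels are needed for the
#' control-replicate coefficient of variation to be defined.
#'
#' @param channels Ordered character vector of channel names.
#' @param roles Character vector, \code{"control"} or \code{"treatment"}
#'   per channel.
#' @param concentrations Molar concentration per channel (NA for
#'   controls; must be > 0 for treatments).
#' @param reporter_mz Optional expected reporter m/z per channel (used by
#'   spectrum simulation/extraction).
#' @param plex Sample/plex identifier.
#' @return data.frame with one row per channel.
#' @examples
#' experimentDesign(c("126", "127N", "127C"), c("control", "control",
#'   "treatment"), c(NA, NA, 1e-6))
#' @export
experimentDesign <- function(channels, roles, concentrations = NA_real_,
                             reporter_mz = NA_real_, plex = "plex1") {
  stopifnot(length(channels) == length(roles),
            all(roles %in% c("control", "treatment")))
  if (anyDuplicated(channels)) stop("channel names must be unique")
  d <- data.frame(channel = as.character(channels), role = roles,
                  concentration_M = rep_len(concentrations, length(channels)),
                  reporter_mz = rep_len(reporter_mz, length(channels)),
                  plex = plex, stringsAsFactors = FALSE)
  trt <- d$concentration_M[d$role == "treatment"]
  if (any(!is.na(trt) & trt <= 0))
    stop("treatment concentrations must be positive")
  d
}

#' TMTpro 16-plex reporter channels
#'
#' Channel names and expected MS3 reporter-ion m/z values for the TMTpro
#' 16-plex reagent set.
#'
#' @return data.frame with columns \code{channel} and \code{mz}.
#' @export
tmtproChannels <- function() {
  data.frame(
    channel = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                "130N", "130C", "131N", "131C", "132N", "132C", "133N",
                "133C", "134N"),
    mz = c(126.127726, 127.124761, 127.131081, 128.128116, 128.134436,
           129.131471, 129.137790, 130.134825, 130.141145, 131.138180,
           131.144500, 132.141535, 132.147855, 133.144890, 133.151210,
           134.148245),
    stringsAsFactors = FALSE)
}

#' Default TMTpro competition design
#'
#' A 16-plex layout with \code{nControls} vehicle (DMSO) replicate channels
#' followed by treatment channels spanning the inhibitor concentration
#' range 1 nM - 10 uM on a log-spaced series, the screening window used for
#' covalent serine-hydrolase inhibitors.
#'
#' @param nControls Number of control replicate channels (default 3).
#' @param concRange Molar range spanned by the treatment channels.
#' @return An [experimentDesign()] data.frame for 16 channels.
#' @export
defaultTmtDesign <- function(nControls = 3, concRange = c(1e-9, 1e-5)) {
  ch <- tmtproChannels()
  n <- nrow(ch)
  stopifnot(nControls >= 2, nControls < n)
  conc <- c(rep(NA_real_, nControls),
            10^seq(log10(concRange[1]), log10(concRange[2]),
                   length.out = n - nControls))
  experimentDesign(ch$channel,
                   c(rep("control", nControls),
                     rep("treatment", n - nControls)),
                   concentrations = conc, reporter_mz = ch$mz)
}

#' @describeIn PsmExperiment-class Design accessor (the colData as a plain
#'   data.frame).
#' @param x A PsmExperiment or a design data.frame.
#' @export
psmDesign <- function(x) as.data.frame(colData(x), stringsAsFactors = FALSE)

#' @describeIn PsmExperiment-class Channels whose role is "control".
#' @export
controlChannels <- function(x) {
  d <- if (is(x, "PsmExperiment")) psmDesign(x) else x
  d$channel[d$role == "control"]
}

#' @describeIn PsmExperiment-class Channels whose role is "treatment".
#' @export
treatmentChannels <- function(x) {
  d <- if (is(x, "PsmExperiment")) psmDesign(x) else x
  d$channel[d$role == "treatment"]
}
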