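#' Extract reporter-ion intensity, noise and SNR from centroided peaks
#'
#' For every spectrum and reporter channel, candidate peaks are those whose
#' m/z lies within \code{window / 2} of the channel's expected mass (the
#' window is a total width: the default 0.002 Th means +/- 0.001 Th; pass
#' \code{halfWindow} to use a half-width directly). The most intense
#' candidate supplies the intensity and its associated noise value, and
#' SNR = intensity / noise. Intensity ties are broken by smaller |delta
#' m/z|, then by lower m/z, so extraction is deterministic. A channel with
#' no in-window peak gets intensity 0, noise NA and SNR 0, so that
#' downstream mean-SNR filters see the missing channel.
#'
#' @param peaks data.frame(\code{spectrum_id}, \code{mz},
#'   \code{intensity}, \code{noise}); intensities and noise must be
#'   positive.
#' @param channels data.frame(\code{channel}, \code{mz}) of expected
#'   reporter masses (default TMTpro 16-plex). Overlapping channel windows
#'   trigger a warning; channels are still resolved independently.
#' @param window Total window width in Th (default 0.002).
#' @param halfWindow Optional half-width in Th; overrides \code{window}.
#' @return data.frame with one row per spectrum x channel:
#'   \code{spectrum_id}, \code{channel}, \code{intensity}, \code{noise},
#'   \code{snr}.
#' @examples
#' pk <- data.frame(spectrum_id = "s1",
#'                  mz = c(126.1277, 126.1290),
#'                  intensity = c(1000, 5000), noise = c(10, 10))
#' extractReporters(pk, data.frame(channel = "126", mz = 126.1277))
#' @export
extractReporters <- function(peaks, channels = tmtproChannels(),
                             window = 0.002, halfWindow = NULL) {
  stopifnot(window > 0,
            all(c("spectrum_id", "mz", "intensity", "noise") %in%
                  names(peaks)))
  if (nrow(peaks) && any(peaks$intensity <= 0 | peaks$noise <= 0))
    stop("peak intensities and noise values must be strictly positive")
  half <- halfWindow %||% (window / 2)
  ord <- order(channels$mz)
  if (nrow(channels) > 1 &&
      any(diff(channels$mz[ord]) < 2 * half))
    warning("reporter channel windows overlap; channels are resolved ",
            "independently")
  ids <- unique(peaks$spectrum_id)
  grid <- expand.grid(spectrum_id = ids, channel = channels$channel,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$expected <- channels$mz[match(grid$channel, channels$channel)]
  bySpec <- split(seq_len(nrow(peaks)), peaks$spectrum_id)
  pick <- function(id, expected) {
    idx <- bySpec[[id]]
    dmz <- abs(peaks$mz[idx] - expected)
    cand <- idx[dmz <= half]
    if (!length(cand)) return(c(0, NA_real_, 0))
    o <- order(-peaks$intensity[cand],
               abs(peaks$mz[cand] - expected), peaks$mz[cand])
    best <- cand[o[1]]
    c(peaks$intensity[best], peaks$noise[best],
      peaks$intensity[best] / peaks$noise[best])
  }
  got <- t(mapply(pick, grid$spectrum_id, grid$expected))
  out <- data.frame(spectrum_id = grid$spectrum_id,
                    channel = grid$channel,
                    intensity = got[, 1], noise = got[, 2], snr = got[, 3],
                    stringsAsFactors = FALSE)
  out[order(match(out$spectrum_id, ids),
            match(out$channel, channels$channel)), , drop = FALSE]
}

#' Assemble a PsmExperiment from peak lists and PSM identifications
#'
#' Runs [extractReporters()] and joins the per-spectrum results onto PSM
#' identifications by \code{spectrum_id}.
#'
#' @param peaks Peak-list data.frame (see [extractReporters()]).
#' @param psmInfo data.frame(\code{spectrum_id}, \code{protein},
#'   \code{peptide}, \code{unique}).
#' @param design [experimentDesign()] with \code{reporter_mz} filled in.
#' @param window,halfWindow Passed to [extractReporters()].
#' @return A [PsmExperiment-class] with assays intensity, noise, snr.
#' @export
psmExperimentFromPeaks <- function(peaks, psmInfo, design,
                                   window = 0.002, halfWindow = NULL) {
  stopifnot(!any(is.na(design$reporter_mz)))
  long <- extractReporters(
    peaks, data.frame(channel = design$channel, mz = design$reporter_mz),
    window = window, halfWindow = halfWindow)
  ids <- psmInfo$spectrum_id
  if (anyDuplicated(ids)) stop("duplicate spectrum_id in psmInfo")
  key <- paste(long$spectrum_id, long$channel, sep = "\r")
  toMat <- function(col, fill) {
    want <- paste(rep(ids, times = nrow(design)),
                  rep(design$channel, each = length(ids)), sep = "\r")
    v <- long[[col]][match(want, key)]
    v[is.na(match(want, key))] <- fill
    matrix(v, nrow = length(ids), ncol = nrow(design),
           dimnames = list(NULL, design$channel))
  }
  PsmExperiment(snr = toMat("snr", 0), rowData = psmInfo, design = design,
                intensity = toMat("intensity", 0),
                noise = toMat("noise", NA_real_))
}
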